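# Shared fixtures and independent oracles for the test suite.

# Build a small network from "a b 0.9" strings (cutoff 0 keeps everything).
make_net <- function(edge_strings, cutoff = 0) {
  parts <- strsplit(edge_strings, "[ \t]+")
  edges <- data.frame(
    from = vapply(parts, `[[`, character(1L), 1L),
    to = vapply(parts, `[[`, character(1L), 2L),
    confidence = vapply(parts, function(p) {
      if (length(p) >= 3L) as.numeric(p[3L]) else 1
    }, numeric(1L)),
    stringsAsFactors = FALSE
  )
  new_network(edges, cutoff = cutoff)
}

# Erdos-Renyi G(n, p) on named nodes, deterministic given seed.
random_net <- function(n, p, seed = 1L, names_prefix = "n") {
  set.seed(seed)
  nodes <- paste0(names_prefix, seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(idx)) < p
  edges <- data.frame(from = nodes[idx[keep, 1L]],
                      to = nodes[idx[keep, 2L]],
                      confidence = 1, stringsAsFactors = FALSE)
  new_network(edges, cutoff = 0, isolated = nodes)
}

# Brute-force crosstalk oracle: double loop over all (q, p) gene pairs,
# counting each network edge at most once.
crosstalk_oracle <- function(qg, pg, net) {
  e <- network_edges(net)
  count <- 0L
  for (i in seq_len(nrow(e))) {
    u <- e$from[i]; v <- e$to[i]
    if ((u %in% qg && v %in% pg) || (v %in% qg && u %in% pg)) {
      count <- count + 1L
    }
  }
  count
}

# Hypergeometric upper-tail oracle by direct pmf-ratio summation (no
# library tail functions, no dhyper): P(X >= k), X ~ Hypergeom(N, K, n).
hyper_upper_oracle <- function(k, N, K, n) {
  kmax <- min(K, n)
  if (k <= 0) return(1)
  if (k > kmax) return(0)
  total <- 0
  for (x in k:kmax) {
    total <- total + choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }
  min(1, total)
}

# Binomial upper-tail oracle by direct summation of choose(n,x) p^x q^(n-x).
binom_upper_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  x <- k:n
  min(1, sum(choose(n, x) * p^x * (1 - p)^(n - x)))
}

# Planted-partition fixture shared across suites (cached per test run).
fixture_cache <- new.env(parent = emptyenv())
get_fixture <- function() {
  if (is.null(fixture_cache$fx)) {
    fixture_cache$fx <- default_fixture()
  }
  fixture_cache$fx
}

# Jaccard between two character sets.
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
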