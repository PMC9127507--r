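# Enrichment statistics. All tail probabilities are computed by explicit
# pmf summation in log space (never 1 - CDF), so small upper-tail p-values
# do not suffer cancellation.

logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (length(x) == 0L) return(-Inf)
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

# P(X >= k) by summing the pmf given as a log-pmf function over k:upper.
upper_tail <- function(k, upper, log_pmf) {
  if (k <= 0L) return(1)
  if (k > upper) return(0)
  min(1, exp(logsumexp(log_pmf(k:upper))))
}

lower_tail <- function(k, lower, log_pmf) {
  if (k < lower) return(0)
  min(1, exp(logsumexp(log_pmf(lower:k))))
}

# One-row enrichment result data.frame (the EnrichmentResult record).
new_result <- function(query, module_id, module_size, pathway, method,
                       observed, expected, p_value,
                       tail = "enrichment", note = "") {
  data.frame(query = query, module_id = module_id,
             module_size = as.integer(module_size), pathway = pathway,
             method = method, observed = as.integer(observed),
             expected = expected, p_value = p_value, q_value = NA_real_,
             tail = tail, note = note, stringsAsFactors = FALSE)
}

#' Overlap enrichment with the EASE adjustment (GEA)
#'
#' Classical gene-overlap enrichment with the conservative EASE adjustment:
#' one is subtracted from the observed overlap before taking the upper
#' hypergeometric tail, so overlaps of fewer than two genes can never be
#' significant (their p-value is exactly 1).
#'
#' @param q,p [gene_set()] objects or character vectors (subsets of the
#'   universe).
#' @param universe_size Number of genes in the universe (at least
#'   `|q union p|`). The usual choice is the network node count.
#' @return A one-row enrichment-result data.frame (method `"GEA"`).
#' @export
gea_test <- function(q, p, universe_size) {
  qg <- set_genes(q); pg <- set_genes(p)
  nq <- length(qg); np <- length(pg)
  if (universe_size < length(union(qg, pg))) {
    stop("universe_size smaller than |q union p|", call. = FALSE)
  }
  k <- length(intersect(qg, pg))
  expected <- nq * np / universe_size
  if (k <= 1L) {
    pv <- 1
  } else {
    # X ~ Hypergeom(N = universe, K = |p| successes, n = |q| draws)
    kmax <- min(nq, np)
    pv <- upper_tail(k - 1L, kmax, function(x) {
      stats::dhyper(x, m = np, n = universe_size - np, k = nq, log = TRUE)
    })
  }
  new_result(set_name(q), "FULL", nq, set_name(p, "pathway"), "GEA",
             observed = k, expected = expected, p_value = pv)
}

#' Hypergeometric crosstalk test (NEAT)
#'
#' Models the crosstalk between a query and a pathway as hypergeometric
#' over the network's half-edge endpoints: of the `2m` endpoints, `d_p`
#' belong to the pathway; the query "draws" its `d_q` endpoints. The
#' expected crosstalk is `d_q * d_p / (2m)`.
#'
#' @param ct A `crosstalk_stat` from [crosstalk()].
#' @param tail `"enrichment"` (P(X >= observed)) or `"depletion"`
#'   (P(X <= observed)).
#' @return A one-row enrichment-result data.frame (method `"NEAT"`).
#' @export
neat_test <- function(ct, tail = c("enrichment", "depletion")) {
  tail <- match.arg(tail)
  stopifnot(inherits(ct, "crosstalk_stat"), ct$m > 0L)
  if (ct$observed > min(ct$d_q, ct$d_p)) {
    stop("internal consistency error: observed crosstalk exceeds min degree mass",
         call. = FALSE)
  }
  two_m <- 2L * ct$m
  expected <- ct$d_q * ct$d_p / two_m
  if (ct$d_q == 0L || ct$d_p == 0L) {
    pv <- if (tail == "enrichment") 1 else 1  # X degenerate at 0
  } else {
    kmax <- min(ct$d_q, ct$d_p)
    log_pmf <- function(x) {
      stats::dhyper(x, m = ct$d_p, n = two_m - ct$d_p, k = ct$d_q, log = TRUE)
    }
    pv <- if (tail == "enrichment") {
      upper_tail(ct$observed, kmax, log_pmf)
    } else {
      lower_tail(ct$observed, 0L, log_pmf)
    }
  }
  new_result(ct$q_name, "FULL", ct$q_size, ct$p_name, "NEAT",
             observed = ct$observed, expected = expected, p_value = pv,
             tail = tail)
}

#' Degree-preserving network randomization
#'
#' Rewires the network by attempted double-edge swaps that preserve every
#' node's degree; swaps creating self-loops or duplicate edges are
#' rejected. Used by [binox_test()] to build its randomized-network null.
#'
#' @param net An `assoc_network`.
#' @param n_swaps_factor Attempted swaps = `n_swaps_factor * |E|`.
#' @param seed Optional RNG seed.
#' @return An `assoc_network` with an identical degree sequence.
#' @export
binox_randomize <- function(net, n_swaps_factor = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- network_edge_count(net)
  g <- net$graph
  if (m >= 2L) {
    g <- igraph::rewire(
      g, igraph::keeping_degseq(loops = FALSE, niter = n_swaps_factor * m))
  }
  structure(list(graph = g, cutoff = net$cutoff, dropped_self_loops = 0L,
                 cache = new.env(parent = emptyenv())),
            class = "assoc_network")
}

# Binomial crosstalk p-value given the estimated per-pair rate.
binox_pvalue <- function(observed, n_possible, p_hat, n_random, tail) {
  eps <- 1 / (n_possible * n_random * 10)
  p_hat <- min(max(p_hat, eps), 1 - eps)
  log_pmf <- function(x) stats::dbinom(x, n_possible, p_hat, log = TRUE)
  pv <- if (tail == "enrichment") {
    upper_tail(observed, n_possible, log_pmf)
  } else {
    lower_tail(observed, 0L, log_pmf)
  }
  list(p_value = pv, expected = n_possible * p_hat, p_hat = p_hat)
}

#' Binomial crosstalk test with network randomization (BinoX)
#'
#' Estimates the per-pair crosstalk rate by averaging the crosstalk of the
#' same two gene sets over degree-preserving randomizations of the network,
#' then tests the observed crosstalk against Binomial(n_possible, p_hat).
#' The rate is clamped away from 0 and 1 by `1/(n_possible *
#' n_random_networks * 10)` to avoid degenerate tails.
#'
#' @param q,p Gene sets mapped to the network.
#' @param net An `assoc_network`.
#' @param n_random_networks Number of randomized networks (default 100).
#' @param seed Optional RNG seed.
#' @param tail `"enrichment"` or `"depletion"`.
#' @param random_nets Optional pre-built list of randomized networks (reused
#'   across many pairs by the pipeline); overrides `n_random_networks`.
#' @return A one-row enrichment-result data.frame (method `"BINOX"`).
#' @export
binox_test <- function(q, p, net, n_random_networks = 100L, seed = NULL,
                       tail = c("enrichment", "depletion"),
                       random_nets = NULL) {
  tail <- match.arg(tail)
  ct <- crosstalk(q, p, net)
  if (ct$n_possible == 0L) {
    stop("untestable pair: zero bipartite capacity", call. = FALSE)
  }
  if (is.null(random_nets)) {
    if (!is.null(seed)) set.seed(seed)
    random_nets <- replicate(n_random_networks,
                             binox_randomize(net), simplify = FALSE)
  }
  qg <- set_genes(map_to_network(q, net, quiet = TRUE))
  pg <- set_genes(map_to_network(p, net, quiet = TRUE))
  null_ct <- vapply(random_nets, function(rn) {
    crosstalk_count(network_adjacency(rn), qg, pg)
  }, integer(1L))
  fit <- binox_pvalue(ct$observed, ct$n_possible,
                      mean(null_ct) / ct$n_possible,
                      length(random_nets), tail)
  new_result(ct$q_name, "FULL", ct$q_size, ct$p_name, "BINOX",
             observed = ct$observed, expected = fit$expected,
             p_value = fit$p_value, tail = tail)
}

#' Null-model specification for sampling-based tests
#'
#' @param mode `"genome_uniform"` (random node sets drawn uniformly from
#'   the network) or `"degree_aware"` (each sampled gene is drawn from the
#'   degree bin of the corresponding query gene, correcting for degree bias
#'   in the query).
#' @param n_samples Number of null gene sets (>= 100; default 2000).
#' @param seed Optional RNG seed.
#' @param bins A `degree_bins` object, required for `"degree_aware"` (built
#'   on demand from the network when omitted).
#' @return A `null_model` list.
#' @export
null_model <- function(mode = c("degree_aware", "genome_uniform"),
                       n_samples = 2000L, seed = NULL, bins = NULL) {
  mode <- match.arg(mode)
  n_samples <- as.integer(n_samples)
  if (n_samples < 100L) stop("n_samples must be at least 100", call. = FALSE)
  structure(list(mode = mode, n_samples = n_samples, seed = seed,
                 bins = bins),
            class = "null_model")
}

#' Sample random gene sets under a null model
#'
#' `genome_uniform` draws sets of the template's size uniformly (without
#' replacement) from the network nodes. `degree_aware` draws, for each
#' template gene, one node from that gene's degree bin; within one sample
#' the draws are without replacement per bin, and a bin holding fewer nodes
#' than the template requires overflows into the nearest neighbouring bins.
#'
#' @param template A [gene_set()] (or character vector) mapped to the
#'   network; for `genome_uniform` a plain integer size is also accepted.
#' @param net An `assoc_network`.
#' @param null A [null_model()].
#' @return A list of `null$n_samples` character vectors of node names,
#'   reproducible from `null$seed`.
#' @export
sample_null_sets <- function(template, net, null) {
  stopifnot(inherits(null, "null_model"))
  if (!is.null(null$seed)) set.seed(null$seed)
  nodes <- network_nodes(net)
  if (null$mode == "genome_uniform") {
    size <- if (is.numeric(template)) as.integer(template)
            else length(set_genes(map_to_network(template, net, quiet = TRUE)))
    if (size < 1L) stop("empty template", call. = FALSE)
    if (size > length(nodes)) stop("template larger than the network", call. = FALSE)
    return(replicate(null$n_samples, sample(nodes, size), simplify = FALSE))
  }
  # degree-aware
  if (is.numeric(template)) {
    stop("degree_aware sampling needs a template gene set, not a size",
         call. = FALSE)
  }
  tg <- set_genes(map_to_network(template, net, quiet = TRUE))
  if (length(tg) == 0L) stop("empty template after mapping", call. = FALSE)
  bins <- null$bins
  if (is.null(bins)) bins <- build_degree_bins(net)
  need <- tabulate(bins$assignment[tg], nbins = nrow(bins$bins))
  lapply(seq_len(null$n_samples), function(i) {
    draw_degree_aware(bins, need)
  })
}

# One degree-aware sample: `need[b]` nodes from bin b, overflowing into the
# nearest bins (by bin-index distance, lower first) when a bin is smaller
# than its demand.
draw_degree_aware <- function(bins, need) {
  nb <- nrow(bins$bins)
  sizes <- lengths(bins$nodes)
  take <- pmin(need, sizes)
  overflow <- need - take
  out <- vector("list", nb)
  for (b in which(take > 0L)) {
    out[[b]] <- if (take[b] == sizes[b]) bins$nodes[[b]]
                else sample(bins$nodes[[b]], take[b])
  }
  for (b in which(overflow > 0L)) {
    rem <- overflow[b]
    for (dist in seq_len(nb)) {
      for (nbhr in c(b - dist, b + dist)) {
        if (rem == 0L) break
        if (nbhr < 1L || nbhr > nb) next
        avail <- setdiff(bins$nodes[[nbhr]], out[[nbhr]])
        if (length(avail) == 0L) next
        k <- min(rem, length(avail))
        picked <- if (k == length(avail)) avail else sample(avail, k)
        out[[nbhr]] <- c(out[[nbhr]], picked)
        rem <- rem - k
      }
      if (rem == 0L) break
    }
    if (rem > 0L) stop("network too small for degree-aware sample", call. = FALSE)
  }
  unlist(out, use.names = FALSE)
}

#' Fit a beta-binomial to null crosstalk counts
#'
#' Method-of-moments fit of BetaBin(n, alpha, beta) to sampled crosstalk
#' counts. When the sample shows no overdispersion relative to the binomial
#' (s^2 <= mean * (1 - mean/n)) or the moment equations give non-positive
#' shapes, the fit falls back to Binomial(n, mean/n) and `fallback` is TRUE.
#'
#' @param samples Integer vector of null crosstalk counts, all in `[0, n]`.
#' @param n Number of trials (the bipartite capacity `n_possible`).
#' @return A `betabin_fit`: `n`, `alpha`, `beta`, `mean`, `var`,
#'   `fallback`, `p_hat`.
#' @export
fit_betabinomial <- function(samples, n) {
  if (length(samples) == 0L) stop("no null samples", call. = FALSE)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (any(samples < 0 | samples > n)) {
    stop("samples outside [0, n]", call. = FALSE)
  }
  xbar <- mean(samples)
  s2 <- stats::var(samples)
  if (is.na(s2)) s2 <- 0
  p <- xbar / n
  fallback <- TRUE
  alpha <- beta <- NA_real_
  binom_var <- xbar * (1 - p)
  if (p > 0 && p < 1 && s2 > binom_var && n > 1L) {
    # s2 = n p (1-p) [1 + (n-1) rho], rho = 1/(alpha+beta+1)
    rho <- (s2 / binom_var - 1) / (n - 1)
    if (rho > 0 && rho < 1) {
      ab <- 1 / rho - 1
      a <- p * ab
      b <- (1 - p) * ab
      if (a > 0 && b > 0) {
        alpha <- a; beta <- b; fallback <- FALSE
      }
    }
  }
  structure(list(n = n, alpha = alpha, beta = beta, mean = xbar, var = s2,
                 fallback = fallback, p_hat = p),
            class = "betabin_fit")
}

#' @exportS3Method base::print
print.betabin_fit <- function(x, ...) {
  if (x$fallback) {
    cat("<betabin_fit> binomial fallback: n=", x$n, ", p=",
        signif(x$p_hat, 4), "\n", sep = "")
  } else {
    cat("<betabin_fit> n=", x$n, ", alpha=", signif(x$alpha, 4),
        ", beta=", signif(x$beta, 4), "\n", sep = "")
  }
  invisible(x)
}

# log pmf of BetaBin(n, alpha, beta)
dbetabin_log <- function(x, n, alpha, beta) {
  lchoose(n, x) + lbeta(x + alpha, n - x + beta) - lbeta(alpha, beta)
}

# P(X >= k) under a betabin_fit, by log-space pmf summation.
betabin_upper <- function(k, fit) {
  if (k <= 0L) return(1)
  if (k > fit$n) return(0)
  log_pmf <- if (fit$fallback) {
    function(x) stats::dbinom(x, fit$n, fit$p_hat, log = TRUE)
  } else {
    function(x) dbetabin_log(x, fit$n, fit$alpha, fit$beta)
  }
  upper_tail(as.integer(k), fit$n, log_pmf)
}

#' Beta-binomial crosstalk test (ANUBIX)
#'
#' Samples random gene sets matching the query (uniformly, or degree-aware
#' through the network's degree bins), computes their crosstalk with the
#' pathway to build the null distribution, fits a beta-binomial (which
#' captures the overdispersion of crosstalk between fixed pathways and
#' random sets), and reports the upper tail at the observed crosstalk.
#' Enrichment only.
#'
#' @param q,p Gene sets mapped to the network.
#' @param net An `assoc_network`.
#' @param null A [null_model()].
#' @param null_samples Optional pre-drawn list of null sets for `q`'s
#'   template (reused across pathways by the pipeline).
#' @return A one-row enrichment-result data.frame (method `"ANUBIX"`).
#' @export
anubix_test <- function(q, p, net, null = null_model(), null_samples = NULL) {
  qm <- map_to_network(q, net, quiet = TRUE)
  if (length(qm$genes) == 0L) {
    return(new_result(set_name(q), "FULL", 0L, set_name(p, "pathway"),
                      "ANUBIX", observed = 0L, expected = NA_real_,
                      p_value = 1, note = "untestable: empty mapped query"))
  }
  ct <- crosstalk(qm, p, net)
  if (ct$n_possible < 1L) {
    stop("untestable pair: zero bipartite capacity", call. = FALSE)
  }
  if (is.null(null_samples)) {
    null_samples <- sample_null_sets(qm, net, null)
  }
  pg <- set_genes(map_to_network(p, net, quiet = TRUE))
  null_ct <- pmin(crosstalk_counts_batch(net, null_samples, pg),
                  ct$n_possible)
  fit <- fit_betabinomial(null_ct, ct$n_possible)
  pv <- betabin_upper(ct$observed, fit)
  new_result(ct$q_name, "FULL", ct$q_size, ct$p_name, "ANUBIX",
             observed = ct$observed,
             expected = fit$mean, p_value = pv)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment, returned in input
#' order (delegates to [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Bonferroni significance threshold
#'
#' Minimal family-wise error-rate helper (used when deciding how many
#' pathways to merge per benchmark query): flags p-values below
#' `alpha / m`.
#'
#' @param p_values Numeric vector of p-values.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Logical vector, TRUE where significant.
#' @export
bonferroni_significant <- function(p_values, alpha = 0.05) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p_values < alpha / length(p_values)
}
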