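#' Specification of a synthetic benchmark fixture
#'
#' Describes a planted-partition association network with degree
#' heterogeneity, plus community-aligned pathways. The default is the
#' package's standard desk-scale fixture: 600 genes in 12 communities of
#' 50, intra-community link probability 0.3 against 0.01 between
#' communities, a hub tail adding `0.2 * n_nodes` preferential edges, and
#' 36 pathways cycling over the communities at three noise levels
#' (0, 10% and 20% of members swapped for random genes).
#'
#' @param n_nodes Total genes.
#' @param n_communities,community_size Planted community structure
#'   (`n_communities * community_size <= n_nodes`).
#' @param p_intra,p_inter Within- and between-community edge probabilities
#'   (`p_intra > p_inter`).
#' @param degree_tail Extra preferential edges as a fraction of `n_nodes`
#'   (0 disables the hub tail).
#' @param pathway_noise Fraction of each pathway's members replaced by
#'   random network genes; a vector is recycled across pathways, giving
#'   distinct noise levels.
#' @param n_pathways Number of pathways (communities are cycled when
#'   `n_pathways > n_communities`).
#' @param seed RNG seed; all generators are pure functions of (spec, seed).
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_nodes = 600L, n_communities = 12L,
                       community_size = 50L, p_intra = 0.3, p_inter = 0.01,
                       degree_tail = 0.2, pathway_noise = c(0, 0.1, 0.2),
                       n_pathways = 36L, seed = 20240501L) {
  stopifnot(p_intra > p_inter, p_inter >= 0, p_intra <= 1,
            degree_tail >= 0, all(pathway_noise >= 0 & pathway_noise <= 1),
            n_communities * community_size <= n_nodes)
  structure(list(n_nodes = as.integer(n_nodes),
                 n_communities = as.integer(n_communities),
                 community_size = as.integer(community_size),
                 p_intra = p_intra, p_inter = p_inter,
                 degree_tail = degree_tail, pathway_noise = pathway_noise,
                 n_pathways = as.integer(n_pathways),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

synth_node_names <- function(n) sprintf("g%04d", seq_len(n))

# Community id per node; nodes beyond the planted blocks get community 0
# (background).
synth_communities <- function(spec) {
  comm <- integer(spec$n_nodes)
  for (c in seq_len(spec$n_communities)) {
    idx <- ((c - 1L) * spec$community_size + 1L):(c * spec$community_size)
    comm[idx] <- c
  }
  comm
}

#' Generate a synthetic association network
#'
#' Planted-partition graph: node pairs within a community link with
#' probability `p_intra`, pairs across communities (or involving background
#' nodes) with `p_inter`. Afterwards `degree_tail * n_nodes` extra edges
#' are attached preferentially to already-high-degree nodes, giving the
#' heavy degree tail that makes the degree-aware null model non-trivial.
#' Edge confidences are drawn uniformly from `[0.8, 1]` so the network
#' behaves like a cutoff-thresholded high-confidence edge list.
#'
#' @param spec A [synth_spec()].
#' @return An `assoc_network` with a `communities` attribute (named integer
#'   vector; 0 = background).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_nodes
  nodes <- synth_node_names(n)
  comm <- synth_communities(spec)
  # planted partition via per-block Bernoulli draws
  pairs_from <- integer(0); pairs_to <- integer(0)
  pm <- outer(comm, comm, function(a, b) {
    ifelse(a == b & a > 0L, spec$p_intra, spec$p_inter)
  })
  ut <- upper.tri(pm)
  draw <- stats::runif(sum(ut)) < pm[ut]
  idx <- which(ut, arr.ind = TRUE)
  pairs_from <- idx[draw, 1L]; pairs_to <- idx[draw, 2L]
  # hub tail: preferential extra edges
  n_extra <- round(spec$degree_tail * n)
  if (n_extra > 0L) {
    deg <- tabulate(c(pairs_from, pairs_to), nbins = n)
    have <- paste(pairs_from, pairs_to)
    added <- 0L
    guard <- 0L
    while (added < n_extra && guard < 50L * n_extra) {
      guard <- guard + 1L
      u <- sample.int(n, 1L, prob = deg + 1)
      v <- sample.int(n, 1L, prob = deg + 1)
      if (u == v) next
      a <- min(u, v); b <- max(u, v)
      key <- paste(a, b)
      if (key %in% have) next
      pairs_from <- c(pairs_from, a); pairs_to <- c(pairs_to, b)
      have <- c(have, key)
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
      added <- added + 1L
    }
  }
  cutoff <- 0.8
  edges <- data.frame(from = nodes[pairs_from], to = nodes[pairs_to],
                      confidence = stats::runif(length(pairs_from),
                                                cutoff, 1),
                      stringsAsFactors = FALSE)
  net <- new_network(edges, cutoff = cutoff, isolated = nodes)
  net$communities <- stats::setNames(comm, nodes)
  net
}

#' Generate community-aligned synthetic pathways
#'
#' Each pathway starts from one community's node set and has
#' `ceil(noise * size)` members swapped for uniformly random other network
#' genes. Pathways cycle over communities when `n_pathways >
#' n_communities`; each carries its community id as a subclass label in the
#' description (`subclass=<id>`), so module-vs-subclass concentration can
#' be checked.
#'
#' @param net A network from [generate_network()] (carries communities).
#' @param spec The same [synth_spec()].
#' @return A [gene_set_collection()] with an attached `subclass` attribute
#'   (named character vector pathway -> community label).
#' @export
generate_pathways <- function(net, spec) {
  stopifnot(inherits(spec, "synth_spec"), !is.null(net$communities))
  set.seed(spec$seed + 1L)
  comm <- net$communities
  nodes <- names(comm)
  noise_levels <- rep_len(spec$pathway_noise, spec$n_pathways)
  sets <- vector("list", spec$n_pathways)
  subclass <- character(spec$n_pathways)
  for (i in seq_len(spec$n_pathways)) {
    c_id <- (i - 1L) %% spec$n_communities + 1L
    members <- nodes[comm == c_id]
    noise <- noise_levels[i]
    n_swap <- ceiling(noise * length(members))
    if (n_swap > 0L) {
      out_idx <- sample(length(members), n_swap)
      pool <- setdiff(nodes, members)
      members[out_idx] <- sample(pool, n_swap)
    }
    nm <- sprintf("P%02d_c%02d", i, c_id)
    sets[[i]] <- gene_set(nm, members,
                          description = sprintf("subclass=c%02d", c_id))
    subclass[i] <- sprintf("c%02d", c_id)
  }
  coll <- gene_set_collection(sets, source = "synthetic")
  attr(coll, "subclass") <- stats::setNames(subclass, names(coll))
  coll
}

#' Generate a multi-pathway query set
#'
#' Emulates an experimentally derived gene set that mixes several
#' functionally distinct pathways: the union of `k` sampled pathways (or of
#' their degree-balanced first halves) plus uniformly random noise genes.
#'
#' @param pathways A [gene_set_collection()].
#' @param k Number of pathways to merge.
#' @param half Use each sampled pathway's first bisection half
#'   ([bisect_pathway()]) instead of the whole pathway.
#' @param noise_genes Number of random network genes added.
#' @param net An `assoc_network`.
#' @param seed RNG seed.
#' @param name Name for the query set.
#' @return A list: `query` ([gene_set()]) and `truth` (character vector of
#'   the sampled pathway names).
#' @export
generate_query <- function(pathways, k, half = FALSE, noise_genes = 0L,
                           net = NULL, seed = NULL, name = "query") {
  stopifnot(inherits(pathways, "gene_set_collection"))
  if (k > length(pathways)) stop("k exceeds the number of pathways", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  picked <- sample(names(pathways), k)
  parts <- lapply(picked, function(nm) {
    g <- pathways[[nm]]$genes
    if (half) {
      halves <- bisect_pathway(pathways[[nm]], net)
      g <- halves[[1L]]$genes
    }
    g
  })
  genes <- unique(unlist(parts))
  if (noise_genes > 0L) {
    stopifnot(!is.null(net))
    pool <- setdiff(network_nodes(net), genes)
    genes <- c(genes, sample(pool, min(noise_genes, length(pool))))
  }
  list(query = gene_set(name, genes), truth = picked)
}

#' Generate a degree-biased gene pool
#'
#' Draws a pool of network genes with selection probability proportional to
#' `degree^bias` (bias 0 = uniform). Random query sets sampled from such a
#' pool have systematically inflated degrees, emulating curated gene-set
#' collections whose members are biased towards well-studied hub genes —
#' the situation where a genome-uniform crosstalk null is miscalibrated and
#' the degree-aware null is needed.
#'
#' @param net An `assoc_network`.
#' @param bias Degree exponent (>= 0).
#' @param seed RNG seed.
#' @param pool_size Pool size (default: a quarter of the network).
#' @return Character vector of gene identifiers (without duplicates).
#' @export
generate_biased_pool <- function(net, bias = 1, seed = NULL,
                                 pool_size = NULL) {
  stopifnot(bias >= 0)
  if (!is.null(seed)) set.seed(seed)
  nodes <- network_nodes(net)
  if (is.null(pool_size)) pool_size <- ceiling(length(nodes) / 4)
  deg <- degree_table(net)[nodes]
  w <- (deg + 1) ^ bias
  sample(nodes, pool_size, prob = w)
}

#' The package's default synthetic fixture
#'
#' Convenience wrapper generating the standard desk-scale fixture (see
#' [synth_spec()]) in one call.
#'
#' @param seed RNG seed (default the fixture's canonical 20240501).
#' @return A list: `net`, `pathways`, `spec`, `subclass`.
#' @export
default_fixture <- function(seed = 20240501L) {
  spec <- synth_spec(seed = seed)
  net <- generate_network(spec)
  pathways <- generate_pathways(net, spec)
  list(net = net, pathways = pathways, spec = spec,
       subclass = attr(pathways, "subclass"))
}
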