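#' Crosstalk between a query set and a pathway
#'
#' Crosstalk is the number of network edges connecting the query gene set to
#' the pathway gene set — the test statistic of all network-based methods in
#' this package. An edge qualifies when one endpoint lies in the query and
#' the other in the pathway; an edge with both endpoints in the overlap
#' counts once. The bipartite capacity is `|q|*|p| - |q intersect p|`
#' (same-gene "pairs" cannot form an edge).
#'
#' @param q,p [gene_set()] objects (or character vectors) already mapped to
#'   the network (see [map_to_network()]).
#' @param net An `assoc_network`.
#' @return A `crosstalk_stat` with fields `observed`, `n_possible`, `d_q`,
#'   `d_p` (total degrees), `m` (network edge count) and the set names.
#' @export
crosstalk <- function(q, p, net) {
  qg <- set_genes(q); pg <- set_genes(p)
  if (length(qg) == 0L || length(pg) == 0L) {
    stop("untestable pair: empty query or pathway after mapping", call. = FALSE)
  }
  if (!all(qg %in% network_nodes(net)) || !all(pg %in% network_nodes(net))) {
    stop("gene set not mapped to the network; call map_to_network() first",
         call. = FALSE)
  }
  adj <- network_adjacency(net)
  obs <- crosstalk_count(adj, qg, pg)
  deg <- degree_table(net)
  structure(
    list(observed = obs,
         n_possible = length(qg) * length(pg) - length(intersect(qg, pg)),
         d_q = sum(deg[qg]), d_p = sum(deg[pg]),
         m = network_edge_count(net),
         q_name = set_name(q), p_name = set_name(p, default = "pathway"),
         q_size = length(qg), p_size = length(pg)),
    class = "crosstalk_stat"
  )
}

#' @exportS3Method base::print
print.crosstalk_stat <- function(x, ...) {
  cat("<crosstalk_stat> ", x$q_name, " vs ", x$p_name, ": observed ",
      x$observed, " of ", x$n_possible, " possible links (d_q=", x$d_q,
      ", d_p=", x$d_p, ", m=", x$m, ")\n", sep = "")
  invisible(x)
}

# Count crossing edges from the sparse adjacency. sum(A[q, p]) counts each
# q->p adjacency once per ordered pair, so edges inside the overlap are
# counted twice; subtract the overlap-internal edge count.
crosstalk_count <- function(adj, qg, pg) {
  s <- sum(adj[qg, pg, drop = FALSE])
  ov <- intersect(qg, pg)
  if (length(ov) > 1L) s <- s - sum(adj[ov, ov, drop = FALSE]) / 2
  as.integer(round(s))
}

# Crosstalk of many sampled gene sets against many pathways in one sweep:
# S %*% A %*% P gives the ordered-pair adjacency mass per (sample, pathway);
# overlap-internal edges (counted twice there) are corrected per pathway on
# the pathway-restricted adjacency block. Returns n_samples x n_pathways.
crosstalk_null_matrix <- function(net, samples, pathway_genes,
                                  prep = NULL) {
  adj <- network_adjacency(net)
  nodes <- rownames(adj)
  n <- length(nodes)
  ns <- length(samples)
  sizes <- lengths(samples)
  si <- rep(seq_len(ns), sizes)
  sj <- match(unlist(samples, use.names = FALSE), nodes)
  S <- Matrix::sparseMatrix(i = si, j = sj, x = 1, dims = c(ns, n))
  if (is.null(prep)) prep <- crosstalk_pathway_prep(net, pathway_genes)
  base <- as.matrix(S %*% prep$AP)
  for (j in seq_along(pathway_genes)) {
    A_j <- prep$blocks[[j]]
    if (is.null(A_j)) next
    S_j <- S[, prep$idx[[j]], drop = FALSE]
    base[, j] <- base[, j] - Matrix::rowSums((S_j %*% A_j) * S_j) / 2
  }
  storage.mode(base) <- "integer"
  base
}

# Pathway-side constants of the null-matrix sweep (shared across all
# templates on one network): AP = adj %*% pathway indicator matrix, plus the
# pathway-internal adjacency blocks for the overlap correction.
crosstalk_pathway_prep <- function(net, pathway_genes) {
  adj <- network_adjacency(net)
  nodes <- rownames(adj)
  n <- length(nodes)
  P <- Matrix::sparseMatrix(
    i = match(unlist(pathway_genes, use.names = FALSE), nodes),
    j = rep(seq_along(pathway_genes), lengths(pathway_genes)),
    x = 1, dims = c(n, length(pathway_genes)))
  idx <- lapply(pathway_genes, match, nodes)
  blocks <- lapply(idx, function(ix) {
    b <- adj[ix, ix, drop = FALSE]
    if (sum(b) == 0) NULL else b
  })
  list(AP = adj %*% P, idx = idx, blocks = blocks)
}

# Crosstalk of many sampled gene sets against one pathway, vectorised.
# samples: list of character vectors of node names; returns integer vector.
crosstalk_counts_batch <- function(net, samples, pg) {
  adj <- network_adjacency(net)
  nodes <- rownames(adj)
  p_ind <- as.numeric(nodes %in% pg)
  idx <- lapply(samples, function(s) match(s, nodes))
  ap <- as.numeric(adj %*% p_ind)           # per-node crossing capacity
  vapply(seq_along(samples), function(i) {
    qi <- idx[[i]]
    s <- sum(ap[qi])
    ov <- qi[p_ind[qi] > 0]
    if (length(ov) > 1L) s <- s - sum(adj[ov, ov, drop = FALSE]) / 2
    as.integer(round(s))
  }, integer(1L))
}

#' Bin network nodes by degree
#'
#' Partitions all network nodes into degree strata used by the degree-aware
#' null model. Degrees are scanned in ascending order; a degree with more
#' than `min_occupancy` nodes forms its own bin, otherwise consecutive
#' degrees accumulate until the running bin holds at least `min_occupancy`
#' nodes. A trailing under-full bin is merged into the previous one (or
#' forms the only bin on small networks).
#'
#' @param net An `assoc_network` (non-empty).
#' @param min_occupancy Minimum nodes per bin (default 100).
#' @return A `degree_bins` object: `bins` (data.frame with `degree_low`,
#'   `degree_high`, `n_nodes`), `nodes` (list of node-name vectors per bin),
#'   `assignment` (named integer vector node -> bin index) and
#'   `min_occupancy`.
#' @export
build_degree_bins <- function(net, min_occupancy = 100L) {
  stopifnot(network_node_count(net) > 0L)
  deg <- degree_table(net)
  degs <- sort(unique(deg))
  lows <- integer(0); highs <- integer(0); members <- list()
  cur_nodes <- character(0); cur_low <- NA_integer_
  for (d in degs) {
    nd <- names(deg)[deg == d]
    if (length(cur_nodes) == 0L) cur_low <- d
    cur_nodes <- c(cur_nodes, nd)
    if (length(cur_nodes) >= min_occupancy) {
      lows <- c(lows, cur_low); highs <- c(highs, d)
      members <- c(members, list(cur_nodes))
      cur_nodes <- character(0)
    }
  }
  if (length(cur_nodes) > 0L) {
    if (length(members) == 0L) {
      lows <- cur_low; highs <- degs[length(degs)]
      members <- list(cur_nodes)
    } else {
      k <- length(members)
      highs[k] <- degs[length(degs)]
      members[[k]] <- c(members[[k]], cur_nodes)
    }
  }
  assignment <- integer(0)
  for (i in seq_along(members)) {
    a <- rep.int(i, length(members[[i]]))
    names(a) <- members[[i]]
    assignment <- c(assignment, a)
  }
  structure(
    list(bins = data.frame(degree_low = lows, degree_high = highs,
                           n_nodes = lengths(members)),
         nodes = members,
         assignment = assignment[network_nodes(net)],
         min_occupancy = as.integer(min_occupancy)),
    class = "degree_bins"
  )
}

#' @exportS3Method base::print
print.degree_bins <- function(x, ...) {
  cat("<degree_bins> ", nrow(x$bins), " bins over degrees [",
      min(x$bins$degree_low), ", ", max(x$bins$degree_high),
      "], min occupancy ", x$min_occupancy, "\n", sep = "")
  invisible(x)
}

#' Induced subgraph of a gene set
#'
#' @param q A [gene_set()] or character vector.
#' @param net An `assoc_network`.
#' @return An `assoc_network` on `q` intersected with the network nodes,
#'   keeping exactly the edges with both endpoints in that set (confidences
#'   preserved).
#' @export
induced_network <- function(q, net) {
  keep <- intersect(set_genes(q), network_nodes(net))
  g <- igraph::induced_subgraph(net$graph, keep)
  structure(
    list(graph = g, cutoff = net$cutoff, dropped_self_loops = 0L,
         cache = new.env(parent = emptyenv())),
    class = "assoc_network"
  )
}
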