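#' Read a functional-association network from a TSV edge list
#'
#' Reads a FunCoup-style tab-separated edge list (`geneA  geneB  confidence`)
#' and keeps the edges whose confidence is at or above `cutoff`. A header
#' line is auto-detected by a non-numeric confidence field. Duplicate rows
#' for the same unordered pair keep the maximum confidence; self-loops are
#' dropped (their count is recorded on the returned object).
#'
#' @param path Path to the edge-list file.
#' @param cutoff Link-confidence cutoff in \[0,1\]; edges below it are
#'   discarded. The conventional default for high-confidence FunCoup links
#'   is 0.8.
#' @param columns Integer vector of length 3: 1-based column indices of
#'   gene A, gene B and the confidence score. FunCoup release files carry
#'   many columns; the default assumes the first three.
#' @return An `assoc_network` object.
#' @export
read_network_tsv <- function(path, cutoff = 0.8, columns = c(1L, 2L, 3L)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 || cutoff > 1) {
    stop("cutoff must be a single number in [0, 1]", call. = FALSE)
  }
  columns <- as.integer(columns)
  stopifnot(length(columns) == 3L, all(columns >= 1L))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty network file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # header auto-detection: non-numeric confidence field on the first row
  first_conf <- suppressWarnings(as.numeric(fields[[1L]][columns[3L]]))
  start <- if (is.na(first_conf)) 2L else 1L
  if (start > length(fields)) stop("network file has a header but no data rows", call. = FALSE)
  n <- length(fields) - start + 1L
  a <- character(n); b <- character(n); w <- numeric(n)
  for (i in seq_len(n)) {
    f <- fields[[start + i - 1L]]
    if (length(f) < max(columns)) {
      stop("malformed row at line ", start + i - 1L, ": fewer than ",
           max(columns), " columns", call. = FALSE)
    }
    conf <- suppressWarnings(as.numeric(f[columns[3L]]))
    if (is.na(conf)) {
      stop("malformed row at line ", start + i - 1L,
           ": confidence not numeric", call. = FALSE)
    }
    a[i] <- f[columns[1L]]; b[i] <- f[columns[2L]]; w[i] <- conf
  }
  edges <- data.frame(from = a, to = b, confidence = w,
                      stringsAsFactors = FALSE)
  new_network(edges, cutoff = cutoff)
}

# Construct an assoc_network from an edge data.frame (from, to, confidence).
# Applies the cutoff, drops self-loops, and keeps the maximum confidence for
# duplicated unordered pairs.
new_network <- function(edges, cutoff, isolated = character()) {
  self <- edges$from == edges$to
  n_self <- sum(self)
  edges <- edges[!self & edges$confidence >= cutoff, , drop = FALSE]
  if (nrow(edges) > 0L) {
    key <- ifelse(edges$from < edges$to,
                  paste(edges$from, edges$to, sep = "\r"),
                  paste(edges$to, edges$from, sep = "\r"))
    o <- order(key, -edges$confidence)
    edges <- edges[o, , drop = FALSE]
    edges <- edges[!duplicated(key[o]), , drop = FALSE]
    rownames(edges) <- NULL
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = unique(c(edges$from, edges$to, isolated))
  )
  if (nrow(edges) > 0L) igraph::E(g)$confidence <- edges$confidence
  if (n_self > 0L) {
    message("dropped ", n_self, " self-loop edge(s)")
  }
  structure(
    list(graph = g, cutoff = cutoff, dropped_self_loops = n_self,
         cache = new.env(parent = emptyenv())),
    class = "assoc_network"
  )
}

#' @exportS3Method base::print
print.assoc_network <- function(x, ...) {
  cat("<assoc_network> ", network_node_count(x), " genes, ",
      network_edge_count(x), " links (confidence cutoff ", x$cutoff, ")\n",
      sep = "")
  invisible(x)
}

#' Network accessors
#'
#' `network_nodes()` returns the gene identifiers, `network_node_count()`
#' and `network_edge_count()` the node and edge counts, and
#' `network_degree()` the (unweighted) degree of every node or of a subset.
#'
#' @param net An `assoc_network`.
#' @param nodes Optional character vector restricting `network_degree()`.
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
network_nodes <- function(net) igraph::V(net$graph)$name

#' @rdname network-accessors
#' @export
network_node_count <- function(net) igraph::vcount(net$graph)

#' @rdname network-accessors
#' @export
network_edge_count <- function(net) igraph::ecount(net$graph)

#' @rdname network-accessors
#' @export
network_degree <- function(net, nodes = NULL) {
  d <- degree_table(net)
  if (is.null(nodes)) d else d[nodes]
}

# Cached degree vector (named, unweighted).
degree_table <- function(net) {
  if (is.null(net$cache$degree)) {
    net$cache$degree <- igraph::degree(net$graph, loops = FALSE)
  }
  net$cache$degree
}

# Cached sparse 0/1 adjacency matrix (dgCMatrix, node order = vertex order).
network_adjacency <- function(net) {
  if (is.null(net$cache$adj)) {
    a <- igraph::as_adjacency_matrix(net$graph, type = "both", sparse = TRUE)
    net$cache$adj <- (a > 0) * 1
  }
  net$cache$adj
}

#' Network edge table
#'
#' @param net An `assoc_network`.
#' @return A data.frame with columns `from`, `to`, `confidence`.
#' @export
network_edges <- function(net) {
  e <- igraph::as_data_frame(net$graph, what = "edges")
  conf <- if ("confidence" %in% names(e)) e$confidence else rep(NA_real_, nrow(e))
  data.frame(from = e$from, to = e$to, confidence = conf,
             stringsAsFactors = FALSE)
}

#' Write a network as a TSV edge list
#'
#' Inverse of [read_network_tsv()]: `read_network_tsv(write_network_tsv(net))`
#' reproduces node set, edge set and confidences.
#'
#' @param net An `assoc_network`.
#' @param path Output path.
#' @export
write_network_tsv <- function(net, path) {
  e <- network_edges(net)
  utils::write.table(e, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Restrict a gene set to network members
#'
#' Query sets routinely contain genes absent from the association network;
#' those cannot contribute crosstalk and are removed before analysis.
#'
#' @param q A [gene_set()] or character vector.
#' @param net An `assoc_network`.
#' @param quiet Suppress the message reporting how many genes were dropped.
#' @return A [gene_set()] with the mapped genes; may be empty (zero-length
#'   `genes`), in which case a plain character(0) carrying the name attribute
#'   is returned inside a degenerate set structure for the caller to handle.
#' @export
map_to_network <- function(q, net, quiet = FALSE) {
  genes <- set_genes(q)
  nm <- set_name(q)
  keep <- genes[genes %in% network_nodes(net)]
  n_removed <- length(genes) - length(keep)
  if (!quiet && n_removed > 0L) {
    message(nm, ": removed ", n_removed, " gene(s) absent from the network")
  }
  structure(list(name = nm, genes = keep, description = ""),
            class = "gene_set")
}

#' Write enrichment results to TSV
#'
#' Columns, in fixed order: query, module_id, module_size, pathway, method,
#' observed, expected, p, q, significant. Rows are sorted by
#' (query, q, p, pathway).
#'
#' @param results A data.frame of enrichment results (as produced by the
#'   test functions or [run_enrichment()]), with columns `query`,
#'   `module_id`, `module_size`, `pathway`, `method`, `observed`,
#'   `expected`, `p_value` and optionally `q_value`.
#' @param path Output path.
#' @param fdr FDR level used to populate the `significant` column
#'   (default 0.05).
#' @export
write_results_tsv <- function(results, path, fdr = 0.05) {
  cols <- c("query", "module_id", "module_size", "pathway", "method",
            "observed", "expected", "p_value", "q_value")
  if (is.null(results) || nrow(results) == 0L) {
    out <- data.frame(query = character(), module_id = character(),
                      module_size = integer(), pathway = character(),
                      method = character(), observed = integer(),
                      expected = numeric(), p = numeric(), q = numeric(),
                      significant = logical())
  } else {
    for (cn in cols) {
      if (!cn %in% names(results)) {
        stop("results missing column '", cn, "'", call. = FALSE)
      }
    }
    out <- results[order(results$query, results$q_value, results$p_value,
                         results$pathway), cols, drop = FALSE]
    names(out)[names(out) == "p_value"] <- "p"
    names(out)[names(out) == "q_value"] <- "q"
    out$significant <- !is.na(out$q) & out$q < fdr
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a results TSV written by [write_results_tsv()]
#'
#' @param path Path to the results file.
#' @return A data.frame in the internal result layout.
#' @export
read_results_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = NA)
  names(df)[names(df) == "p"] <- "p_value"
  names(df)[names(df) == "q"] <- "q_value"
  df
}
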