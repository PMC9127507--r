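#' MCL parameter set
#'
#' Canonical Markov-clustering defaults: expansion 2, inflation 2, unit
#' self-loops to guarantee aperiodicity, light pruning of near-zero
#' transition entries.
#'
#' @param inflation Entrywise power applied at each iteration (> 1).
#' @param expansion Matrix power applied at each iteration (integer >= 2).
#' @param self_loop_weight Weight added on the diagonal before
#'   normalisation (>= 0).
#' @param prune_threshold Entries below this are zeroed (then columns are
#'   renormalised).
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the maximum absolute change of the
#'   transition matrix.
#' @return A `mcl_params` list.
#' @export
mcl_params <- function(inflation = 2, expansion = 2L, self_loop_weight = 1,
                       prune_threshold = 1e-5, max_iter = 200L, tol = 1e-8) {
  stopifnot(inflation > 1, expansion >= 2L, self_loop_weight >= 0,
            prune_threshold >= 0, max_iter >= 1L, tol > 0)
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 self_loop_weight = self_loop_weight,
                 prune_threshold = prune_threshold,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "mcl_params")
}

#' Markov clustering (MCL) of a network
#'
#' Native implementation of flow-simulation clustering: the column-stochastic
#' transition matrix of the (unweighted, self-loop-augmented) graph is
#' alternately expanded (matrix power) and inflated (entrywise power followed
#' by column renormalisation) until it stops changing; clusters are read off
#' the limit matrix as attractor systems and the nodes they attract. The
#' procedure is deterministic — there is no randomness.
#'
#' @param sub An `assoc_network` (typically the query's induced subgraph).
#' @param params An [mcl_params()] object.
#' @param use_weights Use edge confidences instead of 0/1 adjacency
#'   (default FALSE: clustering runs on the cutoff-thresholded, unweighted
#'   graph).
#' @return A list of character vectors, one per cluster, ordered by
#'   decreasing size (ties: lexicographically smallest member first). The
#'   attribute `converged` is FALSE when the iteration cap was hit.
#' @export
mcl_cluster <- function(sub, params = mcl_params(), use_weights = FALSE) {
  stopifnot(inherits(sub, "assoc_network"))
  n <- network_node_count(sub)
  if (n == 0L) stop("cannot cluster an empty graph", call. = FALSE)
  nodes <- network_nodes(sub)
  if (n == 1L) {
    out <- list(nodes)
    attr(out, "converged") <- TRUE
    return(out)
  }
  a <- igraph::as_adjacency_matrix(
    sub$graph, type = "both", sparse = FALSE,
    attr = if (use_weights && network_edge_count(sub) > 0L) "confidence" else NULL
  )
  if (!use_weights) a <- (a > 0) * 1
  diag(a) <- diag(a) + params$self_loop_weight
  m <- normalize_cols(a)
  converged <- FALSE
  for (it in seq_len(params$max_iter)) {
    prev <- m
    # expansion: matrix power
    me <- m
    for (k in seq_len(params$expansion - 1L)) me <- me %*% m
    # inflation: entrywise power + renormalisation, then pruning
    me <- me ^ params$inflation
    me <- normalize_cols(me)
    me[me < params$prune_threshold] <- 0
    m <- normalize_cols(me)
    if (max(abs(m - prev)) < params$tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("MCL did not converge within ", params$max_iter, " iterations",
            call. = FALSE)
  }
  clusters <- mcl_interpret(m, nodes)
  clusters <- order_modules(clusters)
  attr(clusters, "converged") <- converged
  clusters
}

normalize_cols <- function(m) {
  cs <- colSums(m)
  cs[cs == 0] <- 1
  sweep(m, 2L, cs, "/")
}

# Read clusters from the (near-)idempotent limit matrix. Attractors are the
# rows with positive diagonal mass; attractors linked through a shared
# attracted node form one attractor system; every node joins the system(s)
# of the attractors with positive mass in its column. A node attracted to
# two systems goes to the larger one (tie: lexicographically smaller
# smallest-member label).
mcl_interpret <- function(m, nodes) {
  n <- length(nodes)
  eps <- 1e-12
  attractors <- which(diag(m) > eps)
  if (length(attractors) == 0L) {
    # degenerate (non-converged) interpretation: argmax attractor per column
    attractors <- unique(apply(m, 2L, which.max))
  }
  # attractor systems: connected components among attractor rows sharing
  # support (columns) — including each other's columns
  supp <- lapply(attractors, function(i) which(m[i, ] > eps))
  k <- length(attractors)
  sys_id <- seq_len(k)
  repeat {
    changed <- FALSE
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (sys_id[i] != sys_id[j] &&
            length(intersect(supp[[i]], supp[[j]])) > 0L) {
          new_id <- min(sys_id[i], sys_id[j])
          sys_id[sys_id == sys_id[i] | sys_id == sys_id[j]] <- new_id
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  systems <- split(seq_len(k), sys_id)
  members <- lapply(systems, function(rows) {
    sort(unique(unlist(supp[rows])))
  })
  # assign every node: nodes in one system's support only; ambiguous or
  # orphan nodes resolved deterministically
  assign_of <- rep(NA_integer_, n)
  for (s in seq_along(members)) {
    for (v in members[[s]]) {
      if (is.na(assign_of[v])) {
        assign_of[v] <- s
      } else {
        cur <- assign_of[v]
        if (length(members[[s]]) > length(members[[cur]])) {
          assign_of[v] <- s
        } else if (length(members[[s]]) == length(members[[cur]])) {
          cand <- min(nodes[members[[s]]]); inc <- min(nodes[members[[cur]]])
          if (cand < inc) assign_of[v] <- s
        }
      }
    }
  }
  # orphans (all-zero column after pruning): singleton clusters
  orphan <- which(is.na(assign_of))
  clusters <- c(
    lapply(split(seq_len(n)[!is.na(assign_of)],
                 assign_of[!is.na(assign_of)]),
           function(ix) nodes[ix]),
    lapply(orphan, function(v) nodes[v])
  )
  unname(clusters)
}

# Order modules by decreasing size, ties by lexicographically smallest
# member gene; genes inside each module sorted.
order_modules <- function(clusters) {
  clusters <- lapply(clusters, sort)
  sizes <- lengths(clusters)
  firsts <- vapply(clusters, function(x) x[1L], character(1L))
  clusters[order(-sizes, firsts)]
}

# --- clusterer registry -----------------------------------------------------

clusterer_registry <- new.env(parent = emptyenv())

#' Register a clustering backend
#'
#' Backends receive an `assoc_network` (the query's induced subgraph) and a
#' parameter list, and must return a list of character vectors (one per
#' module). `"mcl"` is built in; external partitioners plug in either here
#' or through the command adapter (`method = "adapter:CMD"`, see
#' [partition_query()]).
#'
#' @param name Backend identifier.
#' @param fun Function `(sub, params) -> list of character vectors`.
#' @export
register_clusterer <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = clusterer_registry)
  invisible(name)
}

get_clusterer <- function(name) {
  if (exists(name, envir = clusterer_registry, inherits = FALSE)) {
    return(get(name, envir = clusterer_registry, inherits = FALSE))
  }
  if (startsWith(name, "adapter:")) {
    cmd <- sub("^adapter:", "", name)
    return(function(sub, params) cluster_with_adapter(sub, cmd))
  }
  stop("unknown clusterer '", name, "'; registered: ",
       paste(c(ls(clusterer_registry), "adapter:CMD"), collapse = ", "),
       call. = FALSE)
}

# Adapter contract: the command is run as `CMD edgelist.tsv` where the file
# holds two tab-separated node columns; it must print "node<TAB>module_id"
# lines on stdout. Non-zero exit status is a clustering error. Isolated
# nodes missing from the output become singleton modules.
cluster_with_adapter <- function(sub, cmd) {
  edge_file <- tempfile(fileext = ".tsv")
  on.exit(unlink(edge_file), add = TRUE)
  e <- network_edges(sub)
  utils::write.table(e[, c("from", "to")], edge_file, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  out <- suppressWarnings(system(paste(cmd, shQuote(edge_file)),
                                 intern = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("adapter clusterer '", cmd, "' exited with status ", status,
         call. = FALSE)
  }
  out <- out[nzchar(out)]
  parts <- strsplit(out, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) stop("adapter output line without node<TAB>module_id",
                     call. = FALSE)
  node <- vapply(parts, `[[`, character(1L), 1L)
  mod <- vapply(parts, `[[`, character(1L), 2L)
  labelled <- split(node, mod)
  missing <- setdiff(network_nodes(sub), node)
  c(unname(labelled), as.list(missing))
}

#' Partition a query gene set into network modules
#'
#' Maps the query onto the network, clusters its induced subgraph and
#' returns named modules in decreasing size order (`<query>.m1`,
#' `<query>.m2`, ...). Query genes absent from the network are recorded as
#' unassigned.
#'
#' @param q A [gene_set()] or character vector.
#' @param net An `assoc_network`.
#' @param method Clusterer identifier: `"mcl"` (built in), a name added via
#'   [register_clusterer()], or `"adapter:CMD"` for an external command.
#' @param params Parameters forwarded to the clusterer ([mcl_params()] for
#'   MCL).
#' @return A `module_partition`: `query_name`, `modules` (list of
#'   [gene_set()]), `unassigned` (character vector), `params`, `method`,
#'   `mapped_size`.
#' @export
partition_query <- function(q, net, method = "mcl", params = NULL) {
  fun <- if (identical(method, "mcl")) {
    if (is.null(params)) params <- mcl_params()
    function(sub, p) mcl_cluster(sub, p)
  } else {
    get_clusterer(method)
  }
  qname <- set_name(q)
  mapped <- map_to_network(q, net, quiet = TRUE)
  unassigned <- setdiff(set_genes(q), mapped$genes)
  if (length(mapped$genes) == 0L) {
    return(structure(list(query_name = qname, modules = list(),
                          unassigned = unassigned, params = params,
                          method = method, mapped_size = 0L),
                     class = "module_partition"))
  }
  sub <- induced_network(mapped, net)
  clusters <- fun(sub, params)
  clusters <- order_modules(clusters)
  modules <- lapply(seq_along(clusters), function(i) {
    gene_set(paste0(qname, ".m", i), clusters[[i]])
  })
  structure(list(query_name = qname, modules = modules,
                 unassigned = unassigned, params = params, method = method,
                 mapped_size = length(mapped$genes)),
            class = "module_partition")
}

#' @exportS3Method base::print
print.module_partition <- function(x, ...) {
  sizes <- vapply(x$modules, length, integer(1L))
  cat("<module_partition> ", x$query_name, ": ", length(x$modules),
      " module(s) [", paste(sizes, collapse = ", "), "], ",
      length(x$unassigned), " unassigned (", x$method, ")\n", sep = "")
  invisible(x)
}
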