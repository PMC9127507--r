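#' Benchmark specification
#'
#' Parameters of the pathway-bisection true-positive benchmark: pathways
#' are bisected into degree-balanced halves, ordered by size into
#' `n_bins` bins, and each query merges the first halves of one pathway
#' sampled per bin. The defaults (7 bins, 7 pathways per query, 100
#' queries) give at most 700 true query-pathway associations.
#'
#' @param n_bins Number of size bins (default 7).
#' @param pathways_per_query Pathways merged per query (default 7; must not
#'   exceed `n_bins`).
#' @param n_queries True-positive queries (default 100).
#' @param n_fp_queries Random false-positive queries (default 100).
#' @param overlap_fraction Fraction of each bisection half copied into the
#'   other, emulating overlap between related gene sets (default 0).
#' @param seed RNG seed.
#' @return A `benchmark_spec` list.
#' @export
benchmark_spec <- function(n_bins = 7L, pathways_per_query = 7L,
                           n_queries = 100L, n_fp_queries = 100L,
                           overlap_fraction = 0, seed = 1L) {
  stopifnot(pathways_per_query <= n_bins, n_queries >= 1L,
            overlap_fraction >= 0, overlap_fraction < 1)
  structure(list(n_bins = as.integer(n_bins),
                 pathways_per_query = as.integer(pathways_per_query),
                 n_queries = as.integer(n_queries),
                 n_fp_queries = as.integer(n_fp_queries),
                 overlap_fraction = overlap_fraction,
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Bisect a pathway into degree-balanced halves
#'
#' Splits a pathway's network genes into two halves with as-equal node
#' counts (difference at most 1) and similar total degree: members are
#' sorted by descending degree and assigned greedily to the half with the
#' smaller running total degree, size ties going to the currently smaller
#' half. The resulting total-degree imbalance is bounded by the largest
#' member degree.
#'
#' @param p A [gene_set()].
#' @param net An `assoc_network`.
#' @param seed Optional seed (used only when `overlap_fraction > 0`).
#' @param overlap_fraction After bisection, `ceil(o * |p|)` genes sampled
#'   from each half are copied into the other (default 0).
#' @return A list of two [gene_set()]s (`<name>.h1`, `<name>.h2`), or
#'   `NULL` when fewer than two pathway genes are in the network (skip
#'   signal).
#' @export
bisect_pathway <- function(p, net, seed = NULL, overlap_fraction = 0) {
  genes <- intersect(set_genes(p), network_nodes(net))
  if (length(genes) < 2L) return(NULL)
  deg <- degree_table(net)[genes]
  o <- order(-deg, genes)
  genes <- genes[o]; deg <- deg[o]
  h <- list(character(0), character(0))
  dsum <- c(0, 0); cap <- ceiling(length(genes) / 2)
  for (i in seq_along(genes)) {
    full <- lengths(h) >= cap
    cand <- which(!full)
    pick <- if (length(cand) == 1L) cand else {
      if (dsum[1L] < dsum[2L]) 1L
      else if (dsum[2L] < dsum[1L]) 2L
      else if (length(h[[1L]]) <= length(h[[2L]])) 1L else 2L
    }
    h[[pick]] <- c(h[[pick]], genes[i])
    dsum[pick] <- dsum[pick] + deg[i]
  }
  if (overlap_fraction > 0) {
    if (!is.null(seed)) set.seed(seed)
    n_copy <- ceiling(overlap_fraction * length(genes))
    a_into_b <- sample(h[[1L]], min(n_copy, length(h[[1L]])))
    b_into_a <- sample(h[[2L]], min(n_copy, length(h[[2L]])))
    h[[1L]] <- union(h[[1L]], b_into_a)
    h[[2L]] <- union(h[[2L]], a_into_b)
  }
  nm <- set_name(p, "pathway")
  list(gene_set(paste0(nm, ".h1"), h[[1L]]),
       gene_set(paste0(nm, ".h2"), h[[2L]]))
}

#' Build the bisection true-positive benchmark
#'
#' Bisects every usable pathway (at least two network genes), orders the
#' pathways by size into `n_bins` contiguous bins with as-equal counts
#' (remainder spread over the first bins), and builds each query as the
#' union of the first halves of one pathway sampled per bin (without
#' replacement within a query). Targets are the second halves; the true
#' pairs are all (query, sampled pathway) combinations.
#'
#' @param pathways A [gene_set_collection()].
#' @param net An `assoc_network`.
#' @param spec A [benchmark_spec()].
#' @return A list: `queries` (collection of `n_queries` sets), `targets`
#'   (collection of second halves, named `<pathway>.h2`), `tp_pairs`
#'   (data.frame `query`, `pathway` — pathway names refer to `targets`).
#' @export
build_tp_benchmark <- function(pathways, net, spec = benchmark_spec()) {
  stopifnot(inherits(pathways, "gene_set_collection"))
  set.seed(spec$seed)
  halves <- lapply(pathways$sets, function(p) {
    bisect_pathway(p, net, overlap_fraction = spec$overlap_fraction)
  })
  usable <- !vapply(halves, is.null, logical(1L))
  halves <- halves[usable]
  if (length(halves) < spec$n_bins) {
    stop("need at least ", spec$n_bins, " usable pathways", call. = FALSE)
  }
  sizes <- vapply(pathways$sets[usable], length, integer(1L))
  ord <- names(halves)[order(sizes, names(halves))]
  bins <- split_into_bins(ord, spec$n_bins)
  queries <- vector("list", spec$n_queries)
  tp_q <- character(0); tp_p <- character(0)
  for (i in seq_len(spec$n_queries)) {
    chosen_bins <- if (spec$pathways_per_query == spec$n_bins) {
      seq_len(spec$n_bins)
    } else {
      sort(sample(spec$n_bins, spec$pathways_per_query))
    }
    picked <- vapply(chosen_bins, function(b) sample(bins[[b]], 1L),
                     character(1L))
    first_halves <- unlist(lapply(picked, function(nm) halves[[nm]][[1L]]$genes))
    qname <- sprintf("tpq%03d", i)
    queries[[i]] <- gene_set(qname, unique(first_halves))
    tp_q <- c(tp_q, rep(qname, length(picked)))
    tp_p <- c(tp_p, paste0(picked, ".h2"))
  }
  targets <- gene_set_collection(lapply(halves, `[[`, 2L),
                                 source = "tp-benchmark targets")
  list(queries = gene_set_collection(queries, source = "tp-benchmark"),
       targets = targets,
       tp_pairs = data.frame(query = tp_q, pathway = tp_p,
                             stringsAsFactors = FALSE))
}

# Contiguous bins with as-equal counts; the remainder goes to the first
# bins.
split_into_bins <- function(items, n_bins) {
  n <- length(items)
  base <- n %/% n_bins
  extra <- n %% n_bins
  counts <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  split(items, rep(seq_len(n_bins), counts))
}

#' Build the random-set false-positive benchmark
#'
#' @param net An `assoc_network`.
#' @param size Genes per random set (e.g. the rounded mean true-positive
#'   query size).
#' @param n Number of random sets (default 100).
#' @param seed RNG seed.
#' @param pool Optional gene pool to sample from (default: all network
#'   nodes); see [generate_biased_pool()].
#' @return A [gene_set_collection()] of `n` sets of `size` distinct genes.
#' @export
build_fp_benchmark <- function(net, size, n = 100L, seed = 1L, pool = NULL) {
  if (is.null(pool)) pool <- network_nodes(net)
  pool <- unique(pool)
  if (size > length(pool)) stop("size exceeds the sampling pool", call. = FALSE)
  set.seed(seed)
  sets <- lapply(seq_len(n), function(i) {
    gene_set(sprintf("fpq%03d", i), sample(pool, size))
  })
  gene_set_collection(sets, source = "fp-benchmark")
}

#' Score a benchmark run
#'
#' The true positive rate is the fraction of true (query, pathway) pairs
#' whose merged entry is significant at `q < fdr`; the false positive rate
#' is the fraction of all (random query, pathway) pairs declared
#' significant. The ROC is built by sweeping the pooled merged pairs in
#' order of ascending q (then p); `roc` is restricted to significant pairs
#' (as the curves are usually reported), `roc_full` sweeps everything.
#'
#' @param tp_results List of `pipeline_result`s for the true-positive
#'   queries.
#' @param fp_results List of `pipeline_result`s for the random queries.
#' @param tp_pairs data.frame (`query`, `pathway`) of true associations.
#' @param fdr FDR level (default 0.05).
#' @return A `benchmark_outcome`: `tpr`, `fpr`, `tp_found`, `n_tp_pairs`,
#'   `fp_found`, `n_fp_pairs`, `decisions`, `roc`, `roc_full`.
#' @export
score_benchmark <- function(tp_results, fp_results, tp_pairs, fdr = 0.05) {
  stopifnot(is.data.frame(tp_pairs),
            all(c("query", "pathway") %in% names(tp_pairs)))
  merged_of <- function(res) {
    df <- res$merged
    df$result_query <- res$query
    df
  }
  tp_merged <- do.call(rbind, lapply(tp_results, merged_of))
  fp_merged <- do.call(rbind, lapply(fp_results, merged_of))
  key <- function(q, p) paste(q, p, sep = "\r")
  tp_keys <- key(tp_pairs$query, tp_pairs$pathway)
  sig_tp <- tp_merged[!is.na(tp_merged$q_value) & tp_merged$q_value < fdr, ]
  found <- key(sig_tp$query, sig_tp$pathway)
  n_tp_found <- sum(tp_keys %in% found)
  n_fp_pairs <- if (is.null(fp_merged)) 0L else {
    length(unique(fp_merged$query)) * length(unique(fp_merged$pathway))
  }
  n_fp_found <- if (is.null(fp_merged)) 0L else {
    sum(!is.na(fp_merged$q_value) & fp_merged$q_value < fdr)
  }
  decisions <- rbind(
    if (!is.null(tp_merged))
      data.frame(arm = "tp", query = tp_merged$query,
                 pathway = tp_merged$pathway, p = tp_merged$p_value,
                 q = tp_merged$q_value,
                 is_true = key(tp_merged$query, tp_merged$pathway) %in% tp_keys,
                 significant = !is.na(tp_merged$q_value) & tp_merged$q_value < fdr,
                 stringsAsFactors = FALSE),
    if (!is.null(fp_merged))
      data.frame(arm = "fp", query = fp_merged$query,
                 pathway = fp_merged$pathway, p = fp_merged$p_value,
                 q = fp_merged$q_value, is_true = FALSE,
                 significant = !is.na(fp_merged$q_value) & fp_merged$q_value < fdr,
                 stringsAsFactors = FALSE)
  )
  roc_points <- function(d, n_pos, n_neg) {
    if (nrow(d) == 0L || n_pos == 0L || n_neg == 0L) {
      return(data.frame(fpr = numeric(0), tpr = numeric(0)))
    }
    d <- d[order(d$q, d$p), ]
    # positives counted against the true-pair universe; negatives against
    # the fp-arm pair universe
    tp_cum <- cumsum(d$arm == "tp" & d$is_true)
    fp_cum <- cumsum(d$arm == "fp")
    data.frame(fpr = fp_cum / n_neg, tpr = tp_cum / n_pos)
  }
  structure(
    list(tpr = n_tp_found / nrow(tp_pairs),
         fpr = if (n_fp_pairs > 0L) n_fp_found / n_fp_pairs else 0,
         tp_found = n_tp_found, n_tp_pairs = nrow(tp_pairs),
         fp_found = n_fp_found, n_fp_pairs = n_fp_pairs,
         decisions = decisions,
         roc = roc_points(decisions[decisions$significant, , drop = FALSE],
                          nrow(tp_pairs), n_fp_pairs),
         roc_full = roc_points(decisions, nrow(tp_pairs), n_fp_pairs)),
    class = "benchmark_outcome"
  )
}

#' @exportS3Method base::print
print.benchmark_outcome <- function(x, ...) {
  cat("<benchmark_outcome> TPR ", round(x$tpr, 3), " (", x$tp_found, "/",
      x$n_tp_pairs, "), FPR ", signif(x$fpr, 3), " (", x$fp_found, "/",
      x$n_fp_pairs, ")\n", sep = "")
  invisible(x)
}

#' Pathway-recovery benchmark for a clustering method
#'
#' Repeatedly merges `k` pathways that are pairwise-consecutively linked in
#' the network, clusters the merged set, assigns each module to the pathway
#' with the largest overlap (ties: higher Jaccard, then lexicographic), and
#' scores the Jaccard index between the set of assigned pathways and the
#' set of true pathways.
#'
#' @param pathways A [gene_set_collection()].
#' @param net An `assoc_network`.
#' @param clusterer Clusterer identifier (see [partition_query()]).
#' @param n_sets Number of merged gene sets (default 100).
#' @param k Pathways merged per set (default 3).
#' @param seed RNG seed.
#' @return Numeric vector of `n_sets` recovery Jaccard scores.
#' @export
recovery_benchmark <- function(pathways, net, clusterer = "mcl",
                               n_sets = 100L, k = 3L, seed = 1L) {
  stopifnot(inherits(pathways, "gene_set_collection"))
  set.seed(seed)
  nm <- names(pathways)
  mapped <- lapply(pathways$sets, function(p) {
    intersect(p$genes, network_nodes(net))
  })
  adj <- network_adjacency(net)
  linked <- function(a, b) {
    ga <- mapped[[a]]; gb <- mapped[[b]]
    length(ga) > 0L && length(gb) > 0L &&
      sum(adj[ga, setdiff(gb, ga), drop = FALSE]) > 0
  }
  scores <- numeric(n_sets)
  for (i in seq_len(n_sets)) {
    tuple <- NULL
    for (attempt in seq_len(10000L)) {
      cand <- sample(nm, k)
      ok <- all(vapply(seq_len(k - 1L), function(j) {
        linked(cand[j], cand[j + 1L])
      }, logical(1L)))
      if (ok) { tuple <- cand; break }
    }
    if (is.null(tuple)) {
      stop("no linked ", k, "-tuple of pathways found in 10000 attempts",
           call. = FALSE)
    }
    merged <- gene_set(sprintf("rec%03d", i),
                       unique(unlist(mapped[tuple])))
    part <- partition_query(merged, net, method = clusterer)
    assigned <- vapply(part$modules, function(mod) {
      ov <- vapply(tuple, function(t) {
        length(intersect(mod$genes, mapped[[t]]))
      }, numeric(1L))
      jac <- vapply(tuple, function(t) {
        length(intersect(mod$genes, mapped[[t]])) /
          length(union(mod$genes, mapped[[t]]))
      }, numeric(1L))
      o <- order(-ov, -jac, tuple)
      tuple[o[1L]]
    }, character(1L))
    scores[i] <- length(intersect(unique(assigned), tuple)) /
      length(union(unique(assigned), tuple))
  }
  scores
}

#' Calibrate the module-size filter
#'
#' For a grid of query sizes, runs the clustered pipeline on random gene
#' sets and finds, per size, the minimum integer module-size cutoff that
#' keeps the false positive rate below the configured FDR level. A linear
#' fit of required cutoff against query size through the origin yields the
#' adaptive filter fraction.
#'
#' @param net An `assoc_network`.
#' @param pathways A [gene_set_collection()].
#' @param cfg A [pipeline_config()] (its `filter_fraction` is ignored; the
#'   cutoffs sweep absolute sizes).
#' @param grid Query sizes to calibrate at (default `seq(50, 600, 50)`).
#' @param n_per_size Random sets per size (default 100).
#' @param max_cutoff Largest module-size cutoff tried per size (default:
#'   10% of the query size).
#' @return A `calibration_result`: `grid`, `required_cutoff` (named integer
#'   vector), `fpr_table` (size x cutoff FPR matrix), `fitted_fraction`.
#' @export
calibrate_filter <- function(net, pathways, cfg = pipeline_config(),
                             grid = seq(50L, 600L, by = 50L),
                             n_per_size = 100L, max_cutoff = NULL) {
  stopifnot(all(diff(grid) > 0))
  n_path <- length(pathways)
  required <- integer(length(grid))
  fpr_rows <- list()
  for (gi in seq_along(grid)) {
    size <- grid[gi]
    cutoffs <- 0:(if (is.null(max_cutoff)) max(2L, ceiling(0.1 * size))
                  else max_cutoff)
    sets <- build_fp_benchmark(net, size, n = n_per_size,
                               seed = (cfg$seed %||% 1L) + gi)
    # run once without filtering, then apply cutoffs to the recorded
    # module sizes (increasing the cutoff only removes tests)
    cfg0 <- cfg
    cfg0$filter_fraction <- 0
    results <- lapply(sets$sets, function(s) {
      run_enrichment(s, pathways, net, cfg0)
    })
    fpr_at <- vapply(cutoffs, function(co) {
      n_sig <- 0L
      for (res in results) {
        df <- res$results
        df <- df[df$module_size >= co, , drop = FALSE]
        if (nrow(df) == 0L) next
        df$q_value <- bh_adjust(df$p_value)
        merged <- merge_best_per_pathway(df)
        n_sig <- n_sig + sum(merged$q_value < cfg$fdr, na.rm = TRUE)
      }
      n_sig / (n_per_size * n_path)
    }, numeric(1L))
    ok <- which(fpr_at < cfg$fdr)
    required[gi] <- if (length(ok)) cutoffs[min(ok)] else NA_integer_
    fpr_rows[[gi]] <- data.frame(size = size, cutoff = cutoffs,
                                 fpr = fpr_at)
  }
  names(required) <- grid
  fit_ok <- !is.na(required)
  fitted_fraction <- if (any(fit_ok)) {
    sum(grid[fit_ok] * required[fit_ok]) / sum(grid[fit_ok]^2)
  } else NA_real_
  structure(list(grid = grid, required_cutoff = required,
                 fpr_table = do.call(rbind, fpr_rows),
                 fitted_fraction = fitted_fraction),
            class = "calibration_result")
}

#' @exportS3Method base::print
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> sizes ", min(x$grid), "-", max(x$grid),
      "; fitted filter fraction ", signif(x$fitted_fraction, 3), "\n",
      sep = "")
  print(x$required_cutoff)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
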