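#' Pipeline configuration
#'
#' Bundles every knob of the cluster -> filter -> enrich -> merge pipeline.
#'
#' @param method Enrichment method: `"anubix"`, `"binox"`, `"neat"` or
#'   `"gea"`.
#' @param clusterer Clusterer identifier (`"mcl"`, `"adapter:CMD"`, a
#'   registered name) or `"none"` for un-clustered analysis.
#' @param filter_fraction Adaptive module-size filter: modules smaller than
#'   `filter_fraction * mapped query size` are dropped before testing
#'   (default 0.02, the calibrated 2% rule; see [calibrate_filter()]).
#' @param fdr FDR level for calling significance on BH-adjusted q-values
#'   (default 0.05).
#' @param null A [null_model()] (used by ANUBIX).
#' @param seed Seed applied before the stochastic stages.
#' @param universe_size GEA universe size; `NULL` means the network node
#'   count (the network universe), a number supplies an external genome
#'   size instead.
#' @param bh_scope `"per_query_joint"` (BH jointly over all modules x
#'   pathways of one query) or `"per_module"`.
#' @param mcl [mcl_params()] used when `clusterer = "mcl"`.
#' @param binox_networks Randomized networks for BinoX (default 100).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(method = c("anubix", "binox", "neat", "gea"),
                            clusterer = "mcl", filter_fraction = 0.02,
                            fdr = 0.05, null = null_model(), seed = NULL,
                            universe_size = NULL,
                            bh_scope = c("per_query_joint", "per_module"),
                            mcl = mcl_params(), binox_networks = 100L) {
  method <- match.arg(method)
  bh_scope <- match.arg(bh_scope)
  stopifnot(filter_fraction >= 0, filter_fraction < 1, fdr > 0, fdr < 1)
  structure(list(method = method, clusterer = clusterer,
                 filter_fraction = filter_fraction, fdr = fdr, null = null,
                 seed = seed, universe_size = universe_size,
                 bh_scope = bh_scope, mcl = mcl,
                 binox_networks = as.integer(binox_networks)),
            class = "pipeline_config")
}

#' Adaptive module-size filter
#'
#' Removes modules whose size is strictly below `fraction * query_size`.
#' Small modules are the dominant source of false positives after
#' clustering; filtering at 2% of the query size keeps the false positive
#' rate at the nominal FDR level for methods that control it without
#' clustering.
#'
#' @param partition A `module_partition`.
#' @param query_size Size the threshold is relative to (the mapped query
#'   size in the pipeline).
#' @param fraction Filter fraction in `[0, 1)`.
#' @return The partition with only surviving modules (order and names
#'   preserved); may have zero modules.
#' @export
adaptive_filter <- function(partition, query_size, fraction = 0.02) {
  stopifnot(inherits(partition, "module_partition"),
            fraction >= 0, fraction < 1)
  thr <- fraction * query_size
  keep <- vapply(partition$modules, length, integer(1L)) >= thr
  partition$modules <- partition$modules[keep]
  partition
}

# Test one gene set (query or module) against every pathway with the
# configured method; shared heavy inputs come in via `shared`.
test_against_pathways <- function(gs, module_id, pathways, net, cfg, shared) {
  gm <- map_to_network(gs, net, quiet = TRUE)
  rows <- vector("list", length(pathways))
  null_mat <- NULL
  if (cfg$method == "anubix" && length(gm$genes) > 0L) {
    null_samples <- sample_null_sets(
      gm, net,
      null_model(cfg$null$mode, cfg$null$n_samples, seed = NULL,
                 bins = shared$bins))
    # one sparse sweep computes the null crosstalk of every sample against
    # every pathway
    null_mat <- crosstalk_null_matrix(
      net, null_samples,
      lapply(shared$mapped_pathways, `[[`, "genes"),
      prep = shared$pathway_prep)
  }
  for (j in seq_along(pathways)) {
    pset <- pathways[[j]]
    pm <- shared$mapped_pathways[[j]]
    if (length(gm$genes) == 0L || length(pm$genes) == 0L) {
      r <- new_result(set_name(gs), module_id, length(gm$genes), pset$name,
                      toupper(cfg$method), observed = 0L,
                      expected = NA_real_, p_value = 1,
                      note = "untestable: empty mapped set")
      rows[[j]] <- r
      next
    }
    r <- switch(
      cfg$method,
      gea = gea_test(gm, pm, shared$universe_size),
      neat = neat_test(crosstalk(gm, pm, net)),
      binox = binox_test(gm, pm, net, random_nets = shared$random_nets),
      anubix = {
        ct <- crosstalk(gm, pm, net)
        fit <- fit_betabinomial(pmin(null_mat[, j], ct$n_possible),
                                ct$n_possible)
        new_result(ct$q_name, module_id, ct$q_size, ct$p_name, "ANUBIX",
                   observed = ct$observed, expected = fit$mean,
                   p_value = betabin_upper(ct$observed, fit))
      }
    )
    r$query <- set_name(gs)
    r$pathway <- pset$name
    r$module_id <- module_id
    r$module_size <- length(gm$genes)
    rows[[j]] <- r
  }
  do.call(rbind, rows)
}

#' Run the enrichment pipeline for one query
#'
#' Without clustering (`clusterer = "none"`) the query is tested against
#' every pathway and BH-adjusted over the pathways. With clustering, the
#' query is partitioned on its induced subgraph, small modules are removed
#' by the adaptive size filter, every surviving module is tested against
#' every pathway, q-values are BH-adjusted over the configured scope, and
#' the per-pathway best (minimum-p) module entry forms the merged list.
#' Significant entries are the merged rows with `q < fdr`.
#'
#' @param q A [gene_set()] or character vector.
#' @param pathways A [gene_set_collection()].
#' @param net An `assoc_network`.
#' @param cfg A [pipeline_config()].
#' @return A `pipeline_result`: `query`, `partition` (or NULL), `results`
#'   (all module x pathway rows), `merged` (one row per pathway), and
#'   `significant` (merged rows with `q < fdr`).
#' @export
run_enrichment <- function(q, pathways, net, cfg = pipeline_config()) {
  stopifnot(inherits(pathways, "gene_set_collection"))
  if (length(pathways) == 0L) stop("empty pathway collection", call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  shared <- pipeline_shared(pathways, net, cfg)
  qname <- set_name(q)
  mapped <- map_to_network(q, net, quiet = TRUE)

  if (identical(cfg$clusterer, "none")) {
    partition <- NULL
    if (length(mapped$genes) == 0L) {
      results <- empty_results()
    } else {
      results <- test_against_pathways(mapped, "FULL", pathways, net, cfg,
                                       shared)
      results$q_value <- bh_adjust(results$p_value)
    }
  } else {
    partition <- partition_query(q, net, method = cfg$clusterer,
                                 params = if (identical(cfg$clusterer, "mcl"))
                                   cfg$mcl else NULL)
    partition <- adaptive_filter(partition, partition$mapped_size,
                                 cfg$filter_fraction)
    if (length(partition$modules) == 0L) {
      warning("no modules survive the size filter for query '", qname, "'",
              call. = FALSE)
      results <- empty_results()
    } else {
      chunks <- lapply(partition$modules, function(mod) {
        test_against_pathways(mod, mod$name, pathways, net, cfg, shared)
      })
      if (cfg$bh_scope == "per_module") {
        chunks <- lapply(chunks, function(df) {
          df$q_value <- bh_adjust(df$p_value); df
        })
        results <- do.call(rbind, chunks)
      } else {
        results <- do.call(rbind, chunks)
        results$q_value <- bh_adjust(results$p_value)
      }
      results$query <- qname
    }
  }
  merged <- merge_best_per_pathway(results)
  significant <- merged[!is.na(merged$q_value) & merged$q_value < cfg$fdr, ,
                        drop = FALSE]
  structure(list(query = qname, partition = partition, results = results,
                 merged = merged, significant = significant, config = cfg),
            class = "pipeline_result")
}

empty_results <- function() {
  data.frame(query = character(0), module_id = character(0),
             module_size = integer(0), pathway = character(0),
             method = character(0), observed = integer(0),
             expected = numeric(0), p_value = numeric(0),
             q_value = numeric(0), tail = character(0), note = character(0),
             stringsAsFactors = FALSE)
}

# Heavy inputs shared across modules and queries: mapped pathways, degree
# bins, randomized networks, the GEA universe.
pipeline_shared <- function(pathways, net, cfg) {
  shared <- list(
    mapped_pathways = lapply(pathways$sets, function(p) {
      map_to_network(p, net, quiet = TRUE)
    }),
    universe_size = if (is.null(cfg$universe_size)) network_node_count(net)
                    else cfg$universe_size,
    bins = NULL, random_nets = NULL
  )
  if (cfg$method == "anubix") {
    shared$pathway_prep <- crosstalk_pathway_prep(
      net, lapply(shared$mapped_pathways, `[[`, "genes"))
  }
  if (cfg$method == "anubix" && cfg$null$mode == "degree_aware") {
    shared$bins <- if (!is.null(cfg$null$bins)) cfg$null$bins
                   else build_degree_bins(net)
  }
  if (cfg$method == "binox") {
    shared$random_nets <- replicate(cfg$binox_networks, binox_randomize(net),
                                    simplify = FALSE)
  }
  shared
}

# Per-pathway best entry across modules: minimum p, ties to the larger
# module, then the lexicographically smaller module id.
merge_best_per_pathway <- function(results) {
  if (nrow(results) == 0L) return(results)
  o <- order(results$pathway, results$p_value, -results$module_size,
             results$module_id)
  r <- results[o, , drop = FALSE]
  r <- r[!duplicated(r$pathway), , drop = FALSE]
  r <- r[order(r$q_value, r$p_value, r$pathway), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' @exportS3Method base::print
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> query '", x$query, "' (", x$config$method,
      ", clusterer ", x$config$clusterer, ")\n", sep = "")
  if (!is.null(x$partition)) {
    cat("  modules tested: ", length(x$partition$modules), "\n", sep = "")
  }
  cat("  pathways tested: ", length(unique(x$results$pathway)),
      "; significant at FDR ", x$config$fdr, ": ", nrow(x$significant),
      "\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::summary
summary.pipeline_result <- function(object, ...) {
  top <- utils::head(object$merged[, c("pathway", "module_id", "observed",
                                       "expected", "p_value", "q_value")],
                     10L)
  cat("Top pathways for '", object$query, "':\n", sep = "")
  print(top, row.names = FALSE)
  invisible(object$merged)
}

#' Compare two pipeline runs
#'
#' Compares the significant pathway sets of two runs (typically clustered
#' vs un-clustered analysis of the same query) with the Jaccard index and
#' the fraction of enrichments unique to each run.
#'
#' @param a,b `pipeline_result` objects, or data.frames with `pathway` and
#'   `q_value` columns plus an attached `fdr` attribute.
#' @return A list: `jaccard` (`|A∩B|/|A∪B|`, 1 when both empty),
#'   `unique_to_a` (`|A\\B|/|A|`, 0 when A empty), `unique_to_b`, `n_a`,
#'   `n_b`, `shared`.
#' @export
compare_runs <- function(a, b) {
  sig_names <- function(x) {
    if (inherits(x, "pipeline_result")) x$significant$pathway
    else as.character(x)
  }
  A <- unique(sig_names(a)); B <- unique(sig_names(b))
  u <- union(A, B); i <- intersect(A, B)
  list(
    jaccard = if (length(u) == 0L) 1 else length(i) / length(u),
    unique_to_a = if (length(A) == 0L) 0 else length(setdiff(A, B)) / length(A),
    unique_to_b = if (length(B) == 0L) 0 else length(setdiff(B, A)) / length(B),
    n_a = length(A), n_b = length(B), shared = length(i)
  )
}

#' Subclass concentration of a clustered result
#'
#' For each pathway subclass, how concentrated are its significant pathways
#' on a single module? Returns, per subclass with at least one significant
#' pathway, the fraction of its significant pathways whose best (merged)
#' module is the subclass's modal module.
#'
#' @param result A clustered `pipeline_result`.
#' @param subclass_map Named character vector mapping pathway name ->
#'   subclass.
#' @return Named numeric vector subclass -> concentration in `(0, 1]`;
#'   empty when nothing is significant.
#' @export
subclass_concentration <- function(result, subclass_map) {
  stopifnot(inherits(result, "pipeline_result"))
  if (is.null(result$partition)) {
    stop("subclass concentration needs a clustered result", call. = FALSE)
  }
  sig <- result$significant
  if (nrow(sig) == 0L) return(stats::setNames(numeric(0), character(0)))
  sub <- subclass_map[sig$pathway]
  out <- vapply(split(sig$module_id, sub), function(mods) {
    max(table(mods)) / length(mods)
  }, numeric(1L))
  out
}
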