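test_that("pathway bisection balances size and total degree", {
  # 10-node path graph pathway
  net <- make_net(sprintf("p%d p%d", 1:9, 2:10))
  halves <- bisect_pathway(gene_set("path10", paste0("p", 1:10)), net)
  expect_equal(abs(length(halves[[1]]$genes) - length(halves[[2]]$genes)), 0L)
  deg <- network_degree(net)
  d1 <- sum(deg[halves[[1]]$genes]); d2 <- sum(deg[halves[[2]]$genes])
  expect_lte(abs(d1 - d2), max(deg))
  # the greedy bound holds against every balanced partition's best:
  # exhaustive check that some balanced split achieves the greedy's balance
  combs <- utils::combn(paste0("p", 1:10), 5)
  best <- min(apply(combs, 2, function(h1) {
    abs(sum(deg[h1]) - sum(deg[setdiff(paste0("p", 1:10), h1)]))
  }))
  expect_gte(abs(d1 - d2), best)   # greedy cannot beat the optimum
  expect_lte(abs(d1 - d2), max(deg))

  # 7 members -> 4 + 3
  net7 <- make_net(sprintf("q%d q%d", 1:6, 2:7))
  h7 <- bisect_pathway(gene_set("p7", paste0("q", 1:7)), net7)
  expect_setequal(lengths(lapply(h7, `[[`, "genes")), c(4L, 3L))

  # degenerate single-member pathway: skip signal
  expect_null(bisect_pathway(gene_set("p1", "p1"), net))
})

test_that("bisection size difference is at most one on random instances", {
  for (seed in 1:10) {
    net <- random_net(40, 0.2, seed = seed)
    set.seed(seed)
    sz <- sample(3:15, 1)
    p <- gene_set("p", sample(network_nodes(net), sz))
    halves <- bisect_pathway(p, net)
    expect_lte(abs(length(halves[[1]]$genes) - length(halves[[2]]$genes)), 1L)
    expect_setequal(c(halves[[1]]$genes, halves[[2]]$genes), p$genes)
    deg <- network_degree(net)
    expect_lte(abs(sum(deg[halves[[1]]$genes]) - sum(deg[halves[[2]]$genes])),
               max(deg[p$genes]))
  }
})

test_that("bin splitting spreads the remainder over the first bins", {
  expect_equal(lengths(split_into_bins(paste0("x", 1:35), 7L)),
               rep(5L, 7L), ignore_attr = TRUE)
  expect_equal(lengths(split_into_bins(paste0("x", 1:20), 7L)),
               c(3L, 3L, 3L, 3L, 3L, 3L, 2L), ignore_attr = TRUE)
})

test_that("the TP benchmark builds the full set of true pairs", {
  fx <- get_fixture()
  spec <- benchmark_spec(n_queries = 10L, seed = 23L)
  bm <- build_tp_benchmark(fx$pathways, fx$net, spec)
  expect_equal(length(bm$queries), 10L)
  expect_equal(nrow(bm$tp_pairs), 10L * 7L)
  expect_true(all(bm$tp_pairs$pathway %in% names(bm$targets)))
  # every query equals the union of its sampled first halves
  halves <- lapply(fx$pathways$sets, function(p) bisect_pathway(p, fx$net))
  for (qn in names(bm$queries)[1:3]) {
    picked <- sub("\\.h2$", "", bm$tp_pairs$pathway[bm$tp_pairs$query == qn])
    expected <- unique(unlist(lapply(halves[picked],
                                     function(h) h[[1]]$genes)))
    expect_setequal(bm$queries[[qn]]$genes, expected)
  }
  # determinism
  bm2 <- build_tp_benchmark(fx$pathways, fx$net, spec)
  expect_identical(bm$tp_pairs, bm2$tp_pairs)
})

test_that("the FP benchmark samples distinct genes deterministically", {
  fx <- get_fixture()
  fp <- build_fp_benchmark(fx$net, size = 100L, n = 5L, seed = 77L)
  expect_equal(length(fp), 5L)
  for (s in fp$sets) {
    expect_length(s$genes, 100L)
    expect_false(anyDuplicated(s$genes) > 0)
  }
  fp2 <- build_fp_benchmark(fx$net, size = 100L, n = 5L, seed = 77L)
  expect_identical(lapply(fp$sets, `[[`, "genes"),
                   lapply(fp2$sets, `[[`, "genes"))
  whole <- build_fp_benchmark(fx$net, size = network_node_count(fx$net),
                              n = 1L, seed = 1L)
  expect_setequal(whole[[1L]]$genes, network_nodes(fx$net))
  expect_error(build_fp_benchmark(fx$net, size = 10000L, n = 1L), "pool")
})

fake_result <- function(query, pathways, qvals, module = "FULL") {
  merged <- data.frame(query = query, module_id = module,
                       module_size = 10L, pathway = pathways,
                       method = "ANUBIX", observed = 1L, expected = 1,
                       p_value = qvals, q_value = qvals,
                       tail = "enrichment", note = "",
                       stringsAsFactors = FALSE)
  structure(list(query = query, partition = NULL, results = merged,
                 merged = merged,
                 significant = merged[merged$q_value < 0.05, ],
                 config = pipeline_config()),
            class = "pipeline_result")
}

test_that("score_benchmark computes TPR and FPR from the definitions", {
  tp_pairs <- data.frame(query = c("q1", "q1", "q2", "q2"),
                         pathway = c("P1", "P2", "P1", "P3"),
                         stringsAsFactors = FALSE)
  tp_results <- list(
    fake_result("q1", c("P1", "P2", "P3"), c(0.01, 0.2, 0.9)),
    fake_result("q2", c("P1", "P2", "P3"), c(0.04, 0.01, 0.3))
  )
  fp_results <- list(
    fake_result("f1", c("P1", "P2", "P3"), c(0.01, 0.6, 0.9)),
    fake_result("f2", c("P1", "P2", "P3"), c(0.5, 0.6, 0.9))
  )
  out <- score_benchmark(tp_results, fp_results, tp_pairs, fdr = 0.05)
  # q1-P1 and q2-P1 recovered; q2-P2 significant but not a true pair
  expect_equal(out$tpr, 2 / 4)
  expect_equal(out$fpr, 1 / 6)
  # order invariance
  out2 <- score_benchmark(rev(tp_results), rev(fp_results), tp_pairs)
  expect_equal(out2$tpr, out$tpr)
  expect_equal(out2$fpr, out$fpr)

  # degenerate arms
  none <- score_benchmark(
    list(fake_result("q1", c("P1", "P2"), c(0.9, 0.9))),
    list(fake_result("f1", c("P1", "P2"), c(0.9, 0.9))),
    data.frame(query = "q1", pathway = "P1"))
  expect_equal(none$tpr, 0)
  expect_equal(none$fpr, 0)
  expect_equal(nrow(none$roc), 0L)

  perfect <- score_benchmark(
    list(fake_result("q1", c("P1", "P2"), c(0.01, 0.9))),
    list(fake_result("f1", c("P1", "P2"), c(0.9, 0.9))),
    data.frame(query = "q1", pathway = "P1"))
  expect_equal(perfect$tpr, 1)
  expect_equal(perfect$fpr, 0)
})

test_that("score arithmetic matches the worked example", {
  # 350 of 700 recovered, 100 of 31300 fp pairs significant
  tp_pairs <- data.frame(query = sprintf("q%03d", rep(1:100, each = 7)),
                         pathway = sprintf("P%d", rep(1:7, 100)))
  tp_results <- lapply(sprintf("q%03d", 1:100), function(qn) {
    qv <- rep(0.5, 7); if (match(qn, sprintf("q%03d", 1:100)) <= 50) qv <- rep(0.01, 7)
    fake_result(qn, sprintf("P%d", 1:7), qv)
  })
  fp_results <- lapply(1:100, function(i) {
    qv <- rep(0.5, 313); if (i == 1) qv[1:100] <- 0.01
    fake_result(sprintf("f%03d", i), sprintf("FP%d", 1:313), qv)
  })
  out <- score_benchmark(tp_results, fp_results, tp_pairs)
  expect_equal(out$tpr, 0.5)
  expect_equal(out$fpr, 100 / 31300)
})

test_that("MCL recovers merged planted pathways", {
  fx <- get_fixture()
  noiseless <- fx$pathways[grep("^P(0[1-9]|1[0-2])_", names(fx$pathways))]
  scores <- recovery_benchmark(noiseless, fx$net, clusterer = "mcl",
                               n_sets = 10L, k = 3L, seed = 19L)
  expect_length(scores, 10L)
  expect_gte(mean(scores), 0.9)
})

test_that("filter calibration finds the no-filter case and the regression identity", {
  # identity: required cutoffs exactly 0.02 * size -> fitted fraction 0.02
  grid <- seq(50L, 600L, 50L)
  req <- 0.02 * grid
  frac <- sum(grid * req) / sum(grid^2)
  expect_equal(frac, 0.02, tolerance = 1e-12)

  # a configuration already controlling the FPR needs cutoff 0 everywhere
  # (unpartitioned analysis: the size filter never bites, so the sweep must
  # return 0 at every query size)
  fx <- get_fixture()
  cfg <- pipeline_config(method = "anubix", clusterer = "none",
                         null = null_model("degree_aware", 150L), seed = 3L)
  cal <- calibrate_filter(fx$net, fx$pathways[1:6], cfg,
                          grid = c(60L, 120L), n_per_size = 3L,
                          max_cutoff = 3L)
  expect_equal(unname(cal$required_cutoff), c(0L, 0L))
  expect_true(all(cal$fpr_table$fpr >= 0 & cal$fpr_table$fpr <= 1))
  expect_equal(cal$fitted_fraction, 0)
})

test_that("clustered calibration reports the FPR sweep per cutoff", {
  fx <- get_fixture()
  cfg <- pipeline_config(method = "anubix", clusterer = "mcl",
                         null = null_model("degree_aware", 150L), seed = 5L)
  cal <- calibrate_filter(fx$net, fx$pathways[1:6], cfg, grid = c(80L),
                          n_per_size = 3L, max_cutoff = 4L)
  expect_equal(nrow(cal$fpr_table), 5L)
  expect_true(all(cal$fpr_table$fpr >= 0 & cal$fpr_table$fpr <= 1))
  # the required cutoff is either found within the sweep or flagged NA
  expect_true(is.na(cal$required_cutoff) ||
                cal$required_cutoff %in% 0:4)
})
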