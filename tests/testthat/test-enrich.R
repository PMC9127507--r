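test_that("GEA applies the EASE adjustment and matches enumeration", {
  # overlap of 0 or 1 can never be significant
  r0 <- gea_test(gene_set("q", letters[1:4]), gene_set("p", letters[5:8]), 20)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$expected, 4 * 4 / 20)
  r1 <- gea_test(gene_set("q", letters[1:4]), gene_set("p", letters[4:8]), 20)
  expect_equal(r1$observed, 1L)
  expect_equal(r1$p_value, 1)

  # q = p of size 5 in a universe of 20: p = P(X >= 4), Hypergeom(20, 5, 5)
  q <- gene_set("q", letters[1:5])
  r <- gea_test(q, gene_set("p", letters[1:5]), 20)
  expect_equal(r$p_value, hyper_upper_oracle(4, 20, 5, 5), tolerance = 1e-12)

  # exhaustive over k for all overlap sizes on a small universe
  for (k in 0:6) {
    qg <- paste0("u", 1:8)
    pg <- c(if (k > 0) paste0("u", 1:k), if (k < 6) paste0("v", 1:(6 - k)))
    r <- gea_test(gene_set("q", qg), gene_set("p", pg), 25)
    expected_p <- if (k <= 1) 1 else hyper_upper_oracle(k - 1, 25, 6, 8)
    expect_equal(r$p_value, expected_p, tolerance = 1e-12)
  }
  expect_error(gea_test(gene_set("q", letters[1:10]),
                        gene_set("p", letters[11:20]), 15), "universe")
})

test_that("NEAT expectation and tails follow the half-edge hypergeometric", {
  # m = 50, d_q = 10, d_p = 20 -> expected crosstalk 2
  ct <- structure(list(observed = 4L, n_possible = 30L, d_q = 10L, d_p = 20L,
                       m = 50L, q_name = "q", p_name = "p", q_size = 5L,
                       p_size = 6L),
                  class = "crosstalk_stat")
  r <- neat_test(ct)
  expect_equal(r$expected, 10 * 20 / 100)
  expect_equal(r$p_value, hyper_upper_oracle(4, 100, 20, 10), tolerance = 1e-12)

  # small instance: 2m = 40, d_p = 8, d_q = 6, observed 4
  ct2 <- structure(list(observed = 4L, n_possible = 20L, d_q = 6L, d_p = 8L,
                        m = 20L, q_name = "q", p_name = "p", q_size = 4L,
                        p_size = 4L),
                   class = "crosstalk_stat")
  expect_equal(neat_test(ct2)$p_value, hyper_upper_oracle(4, 40, 8, 6),
               tolerance = 1e-12)
  expect_equal(neat_test(ct2, tail = "depletion")$p_value,
               1 - hyper_upper_oracle(5, 40, 8, 6), tolerance = 1e-12)

  # degenerate degree-0 query
  ct0 <- structure(list(observed = 0L, n_possible = 10L, d_q = 0L, d_p = 8L,
                        m = 20L, q_name = "q", p_name = "p", q_size = 2L,
                        p_size = 5L),
                   class = "crosstalk_stat")
  r0 <- neat_test(ct0)
  expect_equal(r0$expected, 0)
  expect_equal(r0$p_value, 1)
  ct_bad <- ct0; ct_bad$observed <- 5L
  expect_error(neat_test(ct_bad), "consistency")
})

test_that("degree-preserving randomization keeps the degree sequence", {
  net <- random_net(30, 0.2, seed = 4)
  rnd <- binox_randomize(net, seed = 8)
  expect_equal(sort(unname(network_degree(rnd)[network_nodes(net)])),
               sort(unname(network_degree(net))))
  expect_equal(network_edge_count(rnd), network_edge_count(net))

  # 4-cycle: still 4 edges, all degrees 2
  cyc <- make_net(c("a b", "b c", "c d", "d a"))
  r <- binox_randomize(cyc, seed = 1)
  expect_equal(network_edge_count(r), 4)
  expect_true(all(network_degree(r) == 2))

  # triangle admits no valid swap: isomorphic edge set returned
  tri <- make_net(c("a b", "b c", "c a"))
  rt <- binox_randomize(tri, seed = 1)
  e <- network_edges(rt)
  expect_equal(nrow(e), 3L)
  expect_true(all(network_degree(rt) == 2))
})

test_that("binox tail probabilities match direct binomial summation", {
  # fixed p_hat via the internal p-value kernel
  fit <- binox_pvalue(6L, 20L, 0.1, 100L, "enrichment")
  expect_equal(fit$p_value, binom_upper_oracle(6, 20, 0.1), tolerance = 1e-12)
  expect_equal(fit$expected, 2, tolerance = 1e-9)
  # observed 0 -> p = 1
  expect_equal(binox_pvalue(0L, 20L, 0.1, 100L, "enrichment")$p_value, 1)

  # complete graph: randomization cannot change crosstalk
  nodes <- paste0("k", 1:8)
  pairs <- utils::combn(nodes, 2)
  net <- make_net(sprintf("%s %s", pairs[1, ], pairs[2, ]))
  q <- gene_set("q", nodes[1:3]); p <- gene_set("p", nodes[4:6])
  r <- binox_test(q, p, net, n_random_networks = 20, seed = 2)
  # crosstalk is saturated and invariant: expectation equals the observed
  # count up to the degenerate-rate clamp, and the upper tail is mass-heavy
  expect_equal(r$expected, r$observed, tolerance = 1e-2)
  expect_gt(r$p_value, 0.5)
})

test_that("genome-uniform null sampling draws distinct nodes of the right size", {
  net <- random_net(50, 0.1, seed = 30)
  nm <- null_model("genome_uniform", n_samples = 100L, seed = 99L)
  samples <- sample_null_sets(5L, net, nm)
  expect_length(samples, 100L)
  for (s in samples[1:10]) {
    expect_length(s, 5L)
    expect_false(anyDuplicated(s) > 0)
    expect_true(all(s %in% network_nodes(net)))
  }
  # reproducible from seed
  samples2 <- sample_null_sets(5L, net, nm)
  expect_identical(samples, samples2)
})

test_that("degree-aware sampling matches the template's degree profile", {
  # forced case: all template genes in one bin of exactly their size
  net <- make_net(c(sprintf("l%d r%d", 1:6, 1:6),          # degree 1
                    unlist(lapply(1:4, function(i) {
                      sprintf(c("x%d y%d", "y%d z%d", "z%d x%d"), i, i)
                    }))))                                   # degree 2
  bins <- build_degree_bins(net, min_occupancy = 12L)
  expect_equal(nrow(bins$bins), 2L)
  deg1 <- bins$nodes[[1L]]
  tmpl <- gene_set("t", deg1)
  nm <- null_model("degree_aware", n_samples = 100L, seed = 7L, bins = bins)
  samples <- sample_null_sets(tmpl, net, nm)
  for (s in samples[1:5]) expect_setequal(s, deg1)

  # degree-heterogeneous network: degree-aware samples track the template's
  # total degree; uniform samples undershoot for a hub-biased template
  fx <- get_fixture()
  deg <- network_degree(fx$net)
  set.seed(55)
  biased <- sample(names(deg), 50, prob = (deg + 1)^2)
  tmpl2 <- gene_set("biased", biased)
  bins2 <- build_degree_bins(fx$net)
  da <- sample_null_sets(tmpl2, fx$net,
                         null_model("degree_aware", 500L, seed = 11L,
                                    bins = bins2))
  un <- sample_null_sets(tmpl2, fx$net,
                         null_model("genome_uniform", 500L, seed = 11L))
  t_deg <- sum(deg[biased])
  da_mean <- mean(vapply(da, function(s) sum(deg[s]), numeric(1L)))
  un_mean <- mean(vapply(un, function(s) sum(deg[s]), numeric(1L)))
  expect_lt(abs(da_mean - t_deg) / t_deg, 0.05)
  expect_gt(abs(un_mean - t_deg) / t_deg, abs(da_mean - t_deg) / t_deg)
})

test_that("beta-binomial moment fit recovers parameters and degenerates safely", {
  # zero variance -> binomial fallback
  f0 <- fit_betabinomial(rep(3L, 50), 10L)
  expect_true(f0$fallback)
  expect_equal(f0$p_hat, 0.3)

  # independent sampler: X | p ~ Binom(n, p), p ~ Beta(2, 5)
  set.seed(123)
  ps <- rbeta(20000, 2, 5)
  draws <- rbinom(20000, 50, ps)
  fit <- fit_betabinomial(draws, 50L)
  expect_false(fit$fallback)
  expect_gte(fit$alpha, 1.8); expect_lte(fit$alpha, 2.2)
  expect_gte(fit$beta, 4.5); expect_lte(fit$beta, 5.5)
  # MoM identity: fitted mean equals the sample mean
  expect_equal(50 * fit$alpha / (fit$alpha + fit$beta), mean(draws),
               tolerance = 1e-9)

  expect_error(fit_betabinomial(integer(0), 10L), "no null samples")
  expect_error(fit_betabinomial(c(1L, 11L), 10L), "outside")
})

test_that("anubix reduces to the binomial tail when the null is not overdispersed", {
  # fixed null crosstalks [2,3,2,3,...]: variance below binomial -> fallback
  samples <- rep(c(2L, 3L), 25)
  fit <- fit_betabinomial(samples, 50L)
  expect_true(fit$fallback)
  expect_equal(fit$p_hat, 0.05)
  expect_equal(betabin_upper(7L, fit), binom_upper_oracle(7, 50, 0.05),
               tolerance = 1e-12)
  # observed 0 -> p = 1
  expect_equal(betabin_upper(0L, fit), 1)
})

test_that("anubix end-to-end: trivial nulls and determinism", {
  net <- random_net(60, 0.08, seed = 44)
  nodes <- network_nodes(net)
  q <- gene_set("q", nodes[1:8]); p <- gene_set("p", nodes[20:30])
  nm <- null_model("genome_uniform", n_samples = 200L, seed = 5L)
  r1 <- anubix_test(q, p, net, nm)
  r2 <- anubix_test(q, p, net, nm)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 0); expect_lte(r1$p_value, 1)

  # unmapped query -> flagged p = 1
  r0 <- anubix_test(gene_set("ghost", c("zz1", "zz2")), p, net, nm)
  expect_equal(r0$p_value, 1)
  expect_match(r0$note, "untestable")
})

test_that("BH adjustment follows the step-up rule in input order", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(2)
  p <- runif(25)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-15))
  # permutation invariance
  perm <- sample(25)
  expect_equal(bh_adjust(p[perm]), q[perm])
  # monotone in sorted order
  o <- order(p)
  expect_true(!is.unsorted(q[o]))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("the Bonferroni helper thresholds at alpha over m", {
  expect_equal(bonferroni_significant(c(0.004, 0.02, 0.6), alpha = 0.05),
               c(TRUE, FALSE, FALSE))
  expect_equal(bonferroni_significant(0.04), TRUE)
  expect_error(bonferroni_significant(c(0.1, NA)), "0, 1")
})
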