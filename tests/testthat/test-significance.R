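test_that("hypergeometric pmf matches factorial evaluation and sums to 1", {
  expect_equal(hypergeom_pmf(3, 10, 2, 2), 0)  # outside support
  expect_equal(hypergeom_pmf(1, 4, 2, 2), 4 / 6)
  expect_equal(hypergeom_pmf(5, 10, 5, 5), 1 / 252)
  set.seed(91)
  for (i in 1:20) {
    N <- sample(5:60, 1); M <- sample.int(N, 1); K <- sample.int(N, 1)
    support <- max(0, K + M - N):min(K, M)
    pmf <- vapply(support, hypergeom_pmf, numeric(1), N = N, M = M, K = K)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    x <- sample(support, 1)
    expect_equal(hypergeom_pmf(x, N, M, K), oracle_hyper_pmf(x, N, M, K),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_pmf(1, 5, 7, 2), "exceed")
  expect_error(hypergeom_pmf(1, -1, 0, 0), "non-negative")
})

test_that("significance modes implement point-mass and upper-tail tests", {
  r <- significance_test(5, N = 10, M = 5, K = 5, mode = "pmf")
  expect_equal(r$p_value, 1 / 252, tolerance = 1e-12)
  expect_true(r$significant_p)
  # the point-mass test flags a worst-case overlap as 'significant' when
  # the null is spread out: a documented pathology of that mode
  worst <- significance_test(0, N = 100, M = 50, K = 15, mode = "pmf")
  expect_true(worst$significant_p)
  sane <- significance_test(0, N = 100, M = 50, K = 15,
                            mode = "upper_tail")
  expect_false(sane$significant_p)
  expect_equal(sane$p_value, 1)
  # at the support maximum the tail reduces to the point mass
  tailmax <- significance_test(5, N = 10, M = 5, K = 5,
                               mode = "upper_tail")
  expect_equal(tailmax$p_value, 1 / 252, tolerance = 1e-12)
})

test_that("the resampling null matches hypergeometric closed forms", {
  toy <- make_toy_receptor(100, 20, seed = 92)
  # saturate every residue so the sampled pool is the full surface
  ens <- sample_contact_ensemble(toy$structure, toy$annotation,
                                 synthetic_pose_model(n_poses = 2000),
                                 seed = 93)
  prof <- compute_rif(ens, residue_ids(toy$structure))
  N <- length(prof$sampled_residues)
  M <- length(intersect(toy$annotation$interface_residues,
                        prof$sampled_residues))
  K <- 15
  mus <- sapply(1:20, function(s)
    empirical_z(prof, toy$annotation, K = K, reps = 200, seed = s)$mu)
  mu_true <- K * M / N
  sd_true <- sqrt(K * (M / N) * (1 - M / N) * (N - K) / (N - 1))
  expect_lt(abs(mean(mus) - mu_true),
            3 * sd_true / sqrt(200 * 20))
  sigmas <- sapply(1:20, function(s)
    empirical_z(prof, toy$annotation, K = K, reps = 200, seed = s)$sigma)
  expect_lt(abs(mean(sigmas) - sd_true), 0.15 * sd_true)
  # determinism under a fixed seed
  a <- empirical_z(prof, toy$annotation, seed = 7)
  b <- empirical_z(prof, toy$annotation, seed = 7)
  expect_identical(a[c("mu", "sigma", "z")], b[c("mu", "sigma", "z")])
})

test_that("degenerate resampling nulls are rejected with a clear error", {
  universe <- make_res_id("A", 1:20)
  prof <- compute_rif(replicate(50, universe, simplify = FALSE), universe)
  all_iface <- interface_annotation("r", universe)
  expect_error(empirical_z(prof, all_iface, K = 15, seed = 1),
               "degenerate")
  small <- compute_rif(list(universe[1:5]), universe)
  expect_error(empirical_z(small, all_iface, K = 15, seed = 1),
               "smaller than K")
})

test_that("percent significance is a simple flagged fraction", {
  res <- lapply(c(0.01, 0.2, 0.04), function(p) {
    r <- significance_test(0, N = 10, M = 2, K = 2, mode = "pmf")
    r$p_value <- p; r$significant_p <- p < 0.05
    r
  })
  expect_equal(percent_significance(res, "p"), 100 * 2 / 3)
  for (r in seq_along(res)) res[[r]]$significant_p <- TRUE
  expect_equal(percent_significance(res, "p"), 100)
  expect_error(percent_significance(list(), "p"), "no significance")
})

test_that("expected random overlap matches the K^2/N closed form", {
  forced <- expected_random_overlap(15, 15, reps = 50, seed = 94)
  expect_equal(forced$mc_mean, 15)
  expect_equal(forced$mc_sd, 0)
  for (N in c(100, 200)) {
    ov <- expected_random_overlap(N, 15, reps = 200, seed = 95)
    analytic <- 15^2 / N
    expect_equal(ov$analytic, analytic)
    expect_lt(abs(ov$mc_mean - analytic), 3 * ov$mc_sd / sqrt(200))
  }
  expect_error(expected_random_overlap(10, 15), "exceed")
})

test_that("the upper-tail criterion controls type I error under exchangeable draws", {
  # machinery check under the null the hypergeometric model encodes:
  # the prediction is a uniform random K-subset of the sampled pool
  set.seed(96)
  n_rep <- 500L
  flags <- logical(n_rep)
  exact_size <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    N <- sample(120:200, 1); M <- 15L; K <- 15L
    x <- sum(sample.int(N, K) <= M)
    flags[i] <- significance_test(x, N, M, K,
                                  mode = "upper_tail")$significant_p
    # exact size of the discrete test at this N
    xs <- 0:K
    tails <- 1 - phyper(xs - 1, M, N - M, K)
    crit <- xs[which(tails < 0.05)[1]]
    exact_size[i] <- 1 - phyper(crit - 1, M, N - M, K)
  }
  expected <- mean(exact_size)
  expect_lte(expected, 0.05)   # discrete test is conservative
  se <- sqrt(expected * (1 - expected) / n_rep)
  expect_lt(abs(mean(flags) - expected), 3 * se + 1e-9)
})

test_that("enriched ensembles are flagged significant with high power", {
  b <- make_benchmark(30, model = synthetic_pose_model(n_poses = 1000,
                                                       enrichment = 3),
                      seed = 97)
  res <- run_benchmark(b, sig_mode = "upper_tail", seed = 98)
  expect_gte(res$summary$percent_significant_p, 90)
  # p- and z-criteria agree on essentially all clear-signal receptors
  expect_gte(100 * mean(res$per_receptor$significant_p ==
                          res$per_receptor$significant_z), 95)
})
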