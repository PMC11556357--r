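test_that("dB RMSE behaves on identical and offset threshold sets", {
  th <- c(1, 2, 4, 8)
  expect_equal(rmse_dB(th, th), 0)
  expect_equal(rmse_dB(th * 10^(1 / 20), th), 1, tolerance = 1e-10)
  expect_error(rmse_dB(1:3, 1:4), "equal length")
  expect_error(rmse_dB(c(1, -1), c(1, 1)), "positive")
})

test_that("simplex refit of self-generated thresholds is self-consistent and seed-stable", {
  peds <- c(0, 1, 4, 16)
  curves <- lapply(arrangements(), function(a)
    dipper_curve(peds, a, row1))
  fit <- simplex_fit(curves, free = c("omega", "m"), params = row1,
                     n_starts = 12, seed = 5)
  expect_lt(fit$rmse_db, 0.05)
  expect_equal(fit$params$omega, 1.00, tolerance = 0.02)
  expect_equal(fit$params$m, 1.28, tolerance = 0.02)
  fit2 <- simplex_fit(curves, free = c("omega", "m"), params = row1,
                      n_starts = 12, seed = 5)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$best_start, fit2$best_start)
  expect_error(simplex_fit(curves, free = "sigma", params = row1),
               "subset")
})

test_that("simplex matches an exhaustive grid search on a 1-parameter problem", {
  peds <- c(0, 2, 8, 32)
  gen <- gain_params(p = row1$p, q = row1$q, m = row1$m, S = row1$S,
                     Z = row1$Z, omega = 0.7, k = row1$k)
  curves <- lapply(c("binocular", "dichoptic"), function(a)
    dipper_curve(peds, a, gen))
  data <- do.call(rbind, lapply(curves, binocgain:::as_threshold_table))
  # oracle: dense grid over omega
  grid <- seq(0.2, 2, length.out = 400)
  rmse_at <- vapply(grid, function(w) {
    cand <- gain_params(p = row1$p, q = row1$q, m = row1$m, S = row1$S,
                        Z = row1$Z, omega = w, k = row1$k)
    th <- binocgain:::model_thresholds_for(cand, data)
    rmse_dB(th, data$threshold_norm)
  }, numeric(1))
  fit <- simplex_fit(data, free = "omega", params = row1, n_starts = 10,
                     seed = 2)
  expect_lte(fit$rmse_db, min(rmse_at) + 0.05)
  expect_equal(fit$params$omega, 0.7, tolerance = 0.02)
})

test_that("hierarchical Bayesian fit recovers the generating suppression weight", {
  set.seed(611)
  tr <- generate_mocs_dipper(row1, pedestals = c(0, 1, 4, 16),
                             trials_per_level = 40L, n_participants = 3L,
                             jitter_sd = 0.1)
  post <- bayes_fit(tr, mcmc = mcmc_config(n_chains = 1L, n_adapt = 300L,
                                           n_burnin = 300L,
                                           n_iter = 1500L,
                                           retain_fraction = 0.5))
  expect_s3_class(post, "posterior_summary")
  ci_w <- post$intervals[, "wg"]
  expect_true(ci_w[1] <= 1 && 1 <= ci_w[2])
  ci_m <- post$intervals[, "mg"]
  expect_true(ci_m[1] <= 1.28 && 1.28 <= ci_m[2])
  expect_true(all(c("pg", "qg", "mg", "wg", "S", "Z", "kg") %in%
                    colnames(post$samples)))
  expect_equal(post$retained_fraction, 0.5)
})

test_that("cross-pathway Bayesian fit exposes exactly nine free parameters and ranks weights", {
  mech <- list(AC = example_params("bayes_achromatic"),
               RG = example_params("bayes_lm"),
               BY = example_params("bayes_s"))
  W <- matrix(c(0,   0.3, 0.3,
                0.3, 0,   1.0,
                0.3, 0.6, 0), 3, 3, byrow = TRUE)
  gen <- crosspath_model(mech, W)
  set.seed(909)
  tr <- generate_experiment2(gen, n_participants = 2L, jitter_sd = 0.05,
                             design = exp2_design(n_levels = 6L,
                                                  trials_per_block = 60L,
                                                  n_blocks = 2L))
  post <- bayes_fit_crosspath(tr, fixed_model = gen,
                              mcmc = mcmc_config(n_chains = 1L,
                                                 n_adapt = 300L,
                                                 n_burnin = 200L,
                                                 n_iter = 1000L,
                                                 retain_fraction = 0.5))
  expect_equal(ncol(post$samples), 9)  # 3 Z + 6 cross weights
  What <- crosspath_weight_matrix(post, gen, estimate = "median")
  # strongest simulated cross weight (RG target, BY mask) recovered as
  # larger than the weak AC-row weights
  expect_gt(What["RG", "BY"], What["AC", "RG"])
  expect_gt(What["RG", "BY"], What["AC", "BY"])
})
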