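test_that("simulate_trial is a seeded Bernoulli draw", {
  expect_true(all(simulate_trial(rep(1, 50))))
  expect_false(any(simulate_trial(rep(0, 50))))
  expect_error(simulate_trial(1.2), "pc")
  set.seed(33)
  prop <- mean(simulate_trial(rep(0.5, 10000)))
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(prop - 0.5), 3 * se)
  set.seed(7); a <- simulate_trial(rep(0.6, 100))
  set.seed(7); b <- simulate_trial(rep(0.6, 100))
  expect_identical(a, b)
})

test_that("staircase mechanics follow the 3-down-1-up rule in 3 dB steps", {
  set.seed(1)
  sc <- run_staircase(staircase_config(n_trials = 12, start_db = 6),
                      function(l) 1)  # always correct
  expect_equal(sc$trials$level_db, rep(c(6, 3, 0, -3), each = 3))
  set.seed(1)
  sc0 <- run_staircase(staircase_config(n_trials = 6, start_db = 0),
                       function(l) 0)  # always wrong: up every trial
  expect_equal(sc0$trials$level_db, c(0, 3, 6, 9, 12, 15))
  # any observer: consecutive distinct levels differ by exactly 3 dB
  set.seed(14)
  obs <- function(l) 0.5 + 0.5 * pnorm((l - 4) / 3)
  sc2 <- run_staircase(staircase_config(n_trials = 400, start_db = 14),
                       obs)
  steps <- diff(sc2$trials$level_db)
  expect_true(all(abs(steps[steps != 0]) == 3))
})

test_that("staircase reversals converge near the 79.4%-correct point", {
  # 3-down-1-up tracks pc = 0.5^(1/3) = 0.794
  obs <- function(l) 0.5 + 0.5 * pnorm((l - 5) / 4)
  target_pc <- 0.5^(1 / 3)
  target_level <- 5 + 4 * qnorm((target_pc - 0.5) / 0.5)
  set.seed(55)
  revs <- unlist(lapply(1:20, function(i) {
    run_staircase(staircase_config(n_trials = 300, start_db = 15),
                  obs)$reversal_levels
  }))
  expect_gt(length(revs), 200)
  expect_lt(abs(mean(revs) - target_level), 1.5)
})

test_that("participant jitter perturbs only m, omega and k", {
  set.seed(9)
  j <- jitter_params(row1, sd = 0.2)
  expect_identical(j$p, row1$p)
  expect_identical(j$S, row1$S)
  expect_identical(j$Z, row1$Z)
  expect_false(j$m == row1$m)
  set.seed(9)
  j0 <- jitter_params(row1, sd = 0)
  expect_equal(unlist(j0), unlist(row1))
})

test_that("dipper experiment trial counts are exactly determined by the design", {
  d <- exp1_design(trials_per_staircase = 5L, n_reps = 2L)
  d$pedestals_norm <- lapply(d$pedestals_norm, function(x) x[c(1, 4)])
  tr <- generate_experiment1(list(AC = row1), n_participants = 2L,
                             jitter_sd = 0, design = d, seed = 21)
  # 2 participants x 1 pathway x 2 pedestals x 2 reps x 8 staircases x 5
  expect_equal(nrow(tr), 2 * 2 * 2 * 8 * 5)
  expect_setequal(unique(tr$arrangement), arrangements())
  expect_setequal(unique(tr$target_eye), c("left", "right"))
  expect_true(all(tr$target_norm > 0))
  expect_true(all(tr$correct %in% c(0L, 1L)))
  tr3 <- generate_experiment3(row1, n_participants = 1L, jitter_sd = 0,
                              design = d, seed = 3)
  expect_true(all(tr3$experiment == "exp3"))
})

test_that("constant-stimuli masking experiment matches its design arithmetic", {
  des <- tiny_exp2_design()
  tr <- generate_experiment2(n_participants = 2L, design = des, seed = 5)
  # 12 conditions x 2 blocks x 50 trials x 2 participants
  expect_equal(nrow(tr), 12 * 2 * 50 * 2)
  masked <- tr[tr$pathway_mask != "none", ]
  expect_true(all(masked$pedestal_norm == des$mask_norm))
  expect_equal(length(unique(round(
    20 * log10(tr$target_norm[tr$pathway_target == "AC" &
                                tr$pathway_mask == "none"]), 4))),
    des$n_levels)
})

test_that("trial tables round-trip through CSV", {
  tr <- generate_mocs_dipper(row1, pedestals = c(0, 4),
                             arrs = c("monocular", "dichoptic"),
                             trials_per_level = 5L, n_participants = 1L,
                             jitter_sd = 0, seed = 77)
  path <- tempfile(fileext = ".csv")
  write_trial_table(tr, path)
  back <- read_trial_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)
  # malformed tables are rejected with row information
  bad <- tr; bad$correct[3] <- 5L
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(bad), path2, row.names = FALSE)
  expect_error(read_trial_table(path2), "invalid trial rows")
  expect_error(read_trial_table(system.file("DESCRIPTION",
                                            package = "binocgain")),
               "not a trial table")
})

test_that("simulated staircase data recover the generating threshold", {
  # closes the simulate -> fit loop: constant-stimuli data at generative
  # scale recover solve_threshold to better than 0.5 dB
  gen_th <- solve_threshold(4, "binocular", row1)
  tr <- generate_mocs_dipper(row1, pedestals = c(4), arrs = "binocular",
                             level_offsets_db = seq(-8, 8, by = 1.6),
                             trials_per_level = 800L,
                             n_participants = 1L, jitter_sd = 0,
                             seed = 42)
  fit <- fit_psychometric(aggregate_trials(tr))
  expect_lt(abs(fit$threshold_db - 20 * log10(gen_th)), 0.5)
})
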