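test_that("stage-1 response matches hand arithmetic and handles zeros", {
  expect_identical(stage1_response(0, 5, row1), 0)
  expect_equal(stage1_response(1, 0, row1), 1 / (0.99 + 1), tolerance = 1e-10)
  expect_equal(stage1_response(1, 1, row1), 1 / (0.99 + 1 + 1),
               tolerance = 1e-10)
  expect_error(stage1_response(-1, 0, row1), "non-negative")
  expect_error(gain_params(p = 7.99, q = 6.59, m = -1, S = 0.99, Z = 0.08,
                           omega = 1, k = 0.19), "must all be")
})

test_that("stage-1 response is increasing in driving, decreasing in other", {
  set.seed(101)
  for (i in 1:20) {
    p <- random_params()
    cd <- sort(runif(8, 0.01, 30))
    r <- stage1_response(cd, 2, p)
    expect_true(all(diff(r) > 0))
    co <- sort(runif(8, 0, 30))
    r2 <- stage1_response(2, co, p)
    expect_true(all(diff(r2) <= 0))
    expect_true(all(r >= 0) && all(r2 >= 0))
  }
})

test_that("stage-2 nonlinearity and full response behave as specified", {
  # binsum forced to 1 with the classic stage-2 parameters
  expect_equal(binocgain:::stage2_response(1, row1), 1 / 1.08,
               tolerance = 1e-10)
  expect_identical(model_response(0, 0, row1), 0)
  expect_gt(model_response(2, 2, row1), model_response(1, 1, row1))
  # Z = 0 parameter sets stay well-defined at zero contrast
  pz <- example_params("s_grating")
  expect_identical(model_response(0, 0, pz), 0)
})

test_that("arrange_contrasts implements the four ocular arrangements", {
  a <- arrange_contrasts(8, 2, "dichoptic")
  expect_equal(unname(a$target), c(2, 8))
  expect_equal(unname(a$null), c(0, 8))
  h <- arrange_contrasts(4, 1, "half_binocular")
  expect_equal(unname(h$target), c(5, 4))
  expect_equal(unname(h$null), c(4, 4))
  m <- arrange_contrasts(3, 2, "monocular")
  expect_equal(unname(m$target), c(5, 0))
  b <- arrange_contrasts(3, 2, "binocular")
  expect_equal(unname(b$target), c(5, 5))
  # zero target: both intervals identical, in every arrangement
  for (arr in arrangements()) {
    z <- arrange_contrasts(4, 0, arr)
    expect_identical(z$target, z$null)
  }
  # target_eye swaps roles
  r <- arrange_contrasts(8, 2, "dichoptic", target_eye = "right")
  expect_equal(unname(r$target), c(8, 2))
  expect_error(arrange_contrasts(1, 1, "cyclopean"), "unknown arrangement")
})

test_that("d-prime is zero at zero target, tau at threshold, negative in the swan region", {
  expect_identical(dprime(0, 4, "binocular", row1), 0)
  for (arr in arrangements()) {
    th <- solve_threshold(2, arr, row1)
    expect_equal(dprime(th, 2, arr, row1), tau_2ifc(), tolerance = 1e-4)
  }
  expect_lt(dprime(0.5, 16, "dichoptic", row1), 0)
})

test_that("solve_threshold reproduces frozen values and satisfies the criterion", {
  expect_equal(solve_threshold(0, "monocular", row1), 1.348013,
               tolerance = 1e-5)
  th <- solve_threshold(std_pedestals, "dichoptic", row1)
  for (i in seq_along(th)) {
    a <- arrange_contrasts(std_pedestals[i], th[i], "dichoptic")
    diff <- model_response(a$target[["left"]], a$target[["right"]], row1) -
      model_response(a$null[["left"]], a$null[["right"]], row1)
    expect_lt(abs(diff - row1$k), 1e-6 * row1$k)
  }
  # unreachable criterion is an error, never a clamped value
  p_sat <- gain_params(p = 2, q = 3, m = 1.3, S = 1, Z = 0.5, omega = 1,
                       k = 50)
  expect_error(solve_threshold(0, "monocular", p_sat), "no sign change")
})

test_that("solver agrees with a dense grid-search oracle on random draws", {
  # agreement within 0.1 dB where a threshold exists; when the response
  # difference never reaches criterion (possible for m near 1 at high
  # pedestals) both must report failure
  set.seed(202)
  n_checked <- 0; n_tried <- 0
  while (n_checked < 25 && n_tried < 200) {
    n_tried <- n_tried + 1
    p <- random_params()
    arr <- sample(arrangements(), 1)
    ped <- sample(c(0, 0.5, 2, 8, 24), 1)
    th <- try(solve_threshold(ped, arr, p), silent = TRUE)
    or <- try(oracle_threshold(ped, arr, p), silent = TRUE)
    if (inherits(th, "try-error") || inherits(or, "try-error")) {
      expect_true(inherits(th, "try-error") && inherits(or, "try-error"))
      next
    }
    expect_lt(abs(20 * log10(th) - 20 * log10(or)), 0.1)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 25)
})

test_that("dipper curves show facilitation and handle empty/invalid grids", {
  d <- dipper_curve(std_pedestals, "binocular", row1)
  expect_s3_class(d, "dipper_curve")
  expect_equal(nrow(d), 8)
  expect_lt(min(d$threshold_norm),
            d$threshold_norm[d$pedestal_norm == 0])
  dm <- dipper_curve(std_pedestals, "monocular", row1)
  expect_lt(min(dm$threshold_norm),
            dm$threshold_norm[dm$pedestal_norm == 0])
  expect_equal(nrow(dipper_curve(numeric(0), "binocular", row1)), 0)
  expect_error(dipper_curve(c(2, 1), "binocular", row1),
               "strictly increasing")
})

test_that("dipper summaries: handle slope, facilitation, summation ratio", {
  fake <- structure(
    tibble::tibble(pedestal_norm = c(0, 4, 8, 16, 32),
                   threshold_norm = c(1, 4, 8, 16, 32)),
    arrangement = "dichoptic",
    class = c("dipper_curve", "tbl_df", "tbl", "data.frame"))
  expect_equal(summarize_dipper(fake)$handle_slope, 1.0, tolerance = 1e-10)
  dd <- dipper_curve(std_pedestals, "dichoptic", row1)
  s <- summarize_dipper(dd)
  expect_gt(s$handle_slope, 1.0)
  expect_lt(s$handle_slope, 1.1)
  expect_error(summarize_dipper(dipper_curve(c(0, 1, 2), "binocular",
                                             row1)),
               "at least 4")
  # low-contrast limit: summation ratio -> 2^(1/m) within 1%. The
  # criterion must be tiny enough that thresholds fall far below S
  # (thresholds scale as k^(1/(m p)), so k = 1e-4 is only "small" for
  # the m = 1 case where the ratio is exact anyway)
  for (m in c(1.0, 1.28, 2.0)) {
    pk <- gain_params(p = row1$p, q = row1$q, m = m, S = row1$S,
                      Z = row1$Z, omega = 1, k = 1e-30)
    br <- c(1e-8, 1e4)
    ratio <- solve_threshold(0, "monocular", pk, bracket = br,
                             grid_n = 96L) /
      solve_threshold(0, "binocular", pk, bracket = br, grid_n = 96L)
    expect_equal(ratio, 2^(1 / m), tolerance = 0.01)
  }
})

test_that("ocularity invariance and half-binocular ordering hold on the printed grid", {
  for (set in c("meese2006", "achromatic_grating", "lm_grating",
                "s_grating", "flicker_disc")) {
    p <- example_params(set)
    mono <- solve_threshold(std_pedestals[-1], "monocular", p)
    bino <- solve_threshold(std_pedestals[-1], "binocular", p)
    half <- solve_threshold(std_pedestals[-1], "half_binocular", p)
    # convergence of monocular and binocular handles at the top pedestal
    expect_lt(abs(20 * log10(mono[7] / bino[7])), 1)
    # half-binocular never below binocular
    expect_true(all(half >= bino - 1e-9))
  }
})
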