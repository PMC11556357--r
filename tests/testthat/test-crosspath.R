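# a cross-pathway model whose AC mechanism matches the classic achromatic
# row and whose cross weights are all zero: must reduce to the
# single-pathway model exactly
reduced_model <- function(par = row1) {
  mech <- list(AC = par, RG = par, BY = par)
  crosspath_model(mech, matrix(0, 3, 3))
}

test_that("with zero cross weights and one pathway stimulated, the model reduces exactly", {
  m <- reduced_model()
  zero <- c(AC = 0, RG = 0, BY = 0)
  for (c1 in c(0.3, 1, 5)) for (c2 in c(0, 2, 16)) {
    L <- zero; L["AC"] <- c1
    R <- zero; R["AC"] <- c2
    expect_identical(crosspath_stage1(m, L, R, "AC"),
                     stage1_response(c1, c2, row1))
    expect_identical(binocgain:::mechanism_response(m, L, R, "AC"),
                     model_response(c1, c2, row1))
  }
  # dichoptic within-pathway d-prime equals the single-pathway value
  cond <- masking_condition("AC", "AC", 16)
  for (tt in c(0.5, 2, 10, 20)) {
    expect_equal(crosspath_dprime(cond, tt, m),
                 dprime(tt, 16, "dichoptic", row1), tolerance = 1e-12)
  }
})

test_that("cross-pathway suppression matches hand arithmetic", {
  par <- example_params("bayes_achromatic")  # m = 1.27, S = 0.63
  mech <- list(AC = par, RG = par, BY = par)
  W <- matrix(0, 3, 3); W[1, 3] <- 0.5
  m <- crosspath_model(mech, W)
  got <- crosspath_stage1(m, c(AC = 1, RG = 0, BY = 0),
                          c(AC = 0, RG = 0, BY = 16), "AC")
  expect_equal(got, 1 / (0.63 + 1 + 0.5 * 16), tolerance = 1e-10)
  expect_equal(got, 0.1038, tolerance = 1e-3)
})

test_that("unmasked detection sits at tau; zero cross weights leave detection untouched", {
  m <- default_crosspath_model()
  for (pw in pathways()) {
    base <- masking_condition(pw, "none")
    th <- crosspath_threshold(base, m)
    expect_equal(crosspath_dprime(base, th, m), tau_2ifc(),
                 tolerance = 1e-4)
  }
  m0 <- reduced_model()
  base <- masking_condition("AC", "none")
  crossed <- masking_condition("AC", "BY", 16)
  lev <- c(0.5, 1, 2, 4)
  expect_equal(crosspath_dprime(crossed, lev, m0),
               crosspath_dprime(base, lev, m0), tolerance = 1e-12)
})

test_that("within-pathway dichoptic masking produces a swan region", {
  m <- default_crosspath_model()
  for (pw in pathways()) {
    cond <- masking_condition(pw, pw, 16)
    dp <- crosspath_dprime(cond, seq(0.2, 2, by = 0.2), m)
    expect_true(any(dp < 0))
    pc <- predict_psychometric(cond, seq(0.2, 2, by = 0.2), m,
                               lapse = 0)
    expect_true(any(pc < 0.5))
  }
})

test_that("the psychometric link maps d-prime 0 to chance for any lapse", {
  expect_equal(dprime_to_pc(0), 0.5)
  expect_equal(dprime_to_pc(0, lapse = 0.04), 0.5)
  expect_equal(dprime_to_pc(tau_2ifc()), 0.75, tolerance = 1e-10)
  expect_error(dprime_to_pc(1, lapse = 2), "lapse")
})

test_that("within-pathway masks shift the 75% point furthest right", {
  m <- default_crosspath_model()
  for (pw in pathways()) {
    ths <- vapply(pathways(), function(mask) {
      crosspath_threshold(masking_condition(pw, mask, 16), m)
    }, numeric(1))
    expect_equal(names(which.max(ths)), pw)
  }
})

test_that("threshold elevation is monotone in the suppressive weight", {
  par <- example_params("bayes_achromatic")
  mech <- list(AC = par, RG = par, BY = par)
  base_th <- NULL
  last <- -Inf
  for (w in c(0, 0.3, 0.6, 1.0, 1.5)) {
    W <- matrix(0, 3, 3); W[1, 3] <- w
    m <- crosspath_model(mech, W)
    th <- crosspath_threshold(masking_condition("AC", "BY", 16), m)
    if (w == 0) base_th <- th
    expect_gte(th, last - 1e-9)
    last <- th
  }
  expect_gt(last / base_th, 1)  # strong weight raises threshold
})

test_that("elevation matrix peaks on the diagonal for modest cross weights", {
  mech <- list(AC = example_params("bayes_achromatic"),
               RG = example_params("bayes_lm"),
               BY = example_params("bayes_s"))
  W <- matrix(0.5, 3, 3)
  m <- crosspath_model(mech, W)
  elev <- matrix(NA_real_, 3, 3, dimnames = list(pathways(), pathways()))
  for (tp in pathways()) {
    b <- crosspath_threshold(masking_condition(tp, "none"), m)
    for (mp in pathways()) {
      elev[tp, mp] <-
        crosspath_threshold(masking_condition(tp, mp, 16), m) / b
    }
  }
  for (tp in pathways()) {
    expect_equal(names(which.max(elev[tp, ])), tp)
  }
})
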