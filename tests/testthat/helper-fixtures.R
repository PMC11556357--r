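options(binocgain.verbose = FALSE)

# classic achromatic parameter row used throughout
row1 <- example_params("meese2006")

std_pedestals <- c(0, 0.5, 1, 2, 4, 8, 16, 32)

# brute-force threshold oracle: dense log grid, first upward crossing of
# the criterion, then local refinement by uniroot. Independent of the
# package's vectorized bisection path.
oracle_threshold <- function(pedestal, arrangement, params, n_grid = 3000) {
  f <- function(tt) {
    a <- arrange_contrasts(pedestal, tt, arrangement)
    model_response(a$target[["left"]], a$target[["right"]], params) -
      model_response(a$null[["left"]], a$null[["right"]], params) -
      params$k
  }
  g <- exp(seq(log(1e-4), log(1e4), length.out = n_grid))
  v <- vapply(g, f, numeric(1))
  i <- which(v > 0)[1]
  if (is.na(i) || i == 1) stop("oracle: no crossing")
  stats::uniroot(f, lower = g[i - 1], upper = g[i], tol = 1e-12)$root
}

# random-but-valid parameter draw for property tests; q < p as in every
# published fit (q >= p saturates the transducer and thresholds need not
# exist at high pedestals)
random_params <- function() {
  p <- runif(1, 4, 12)
  gain_params(p = p, q = p * runif(1, 0.6, 0.95),
              m = runif(1, 1.0, 1.6), S = runif(1, 0.3, 1.5),
              Z = runif(1, 0.01, 0.5), omega = runif(1, 0.3, 1.2),
              k = runif(1, 0.05, 0.5))
}

# small, fast designs for pipeline tests
tiny_exp1_design <- function() {
  d <- exp1_design(trials_per_staircase = 8L, n_reps = 1L)
  d$pedestals_norm <- lapply(d$pedestals_norm, function(x) x[c(1, 3, 5)])
  d
}

tiny_exp2_design <- function() {
  exp2_design(n_levels = 5L, trials_per_block = 50L, n_blocks = 2L)
}
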