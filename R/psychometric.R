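#' Contrast / decibel conversion
#'
#' \eqn{C_{dB} = 20 \log_{10}(C)}, the standard dB re 1% convention when
#' `contrast` is expressed in percent.
#'
#' @param contrast Contrast value(s) > 0 (typically percent).
#' @param db dB value(s).
#' @return `to_dB()` the dB values; `from_dB()` the linear contrasts.
#' @export
#' @examples
#' to_dB(10)   # 20
#' from_dB(40) # 100
to_dB <- function(contrast) {
  if (any(!is.finite(contrast)) || any(contrast <= 0)) {
    stop("contrast must be finite and > 0", call. = FALSE)
  }
  20 * log10(contrast)
}

#' @rdname to_dB
#' @export
from_dB <- function(db) 10^(db / 20)

#' Binomial counts per stimulus level
#'
#' @param levels_db Stimulus levels in dB.
#' @param n_correct Correct responses at each level.
#' @param n_total Trials at each level.
#' @return An object of class `level_counts`.
#' @export
level_counts <- function(levels_db, n_correct, n_total) {
  if (length(levels_db) != length(n_correct) ||
      length(levels_db) != length(n_total)) {
    stop("levels_db, n_correct and n_total must have equal length",
         call. = FALSE)
  }
  if (any(n_total <= 0) || any(n_correct < 0) || any(n_correct > n_total)) {
    stop("need 0 <= n_correct <= n_total and n_total > 0", call. = FALSE)
  }
  o <- order(levels_db)
  structure(list(levels_db = as.numeric(levels_db)[o],
                 n_correct = as.integer(round(n_correct))[o],
                 n_total = as.integer(round(n_total))[o]),
            class = "level_counts")
}

#' Aggregate a trial table into binomial level counts
#'
#' Groups trials by target level (dB of the normalized target contrast)
#' and counts correct responses — the input format for
#' [fit_psychometric()].
#'
#' @param trials A trial-table tibble (see [read_trial_table()]),
#'   pre-filtered to a single condition.
#' @param digits Rounding applied to the dB levels before grouping
#'   (guards against floating-point level duplication).
#' @return A [level_counts()] object.
#' @export
aggregate_trials <- function(trials, digits = 6) {
  lev <- round(20 * log10(trials$target_norm), digits)
  agg <- stats::aggregate(cbind(nc = trials$correct,
                                nt = rep(1L, nrow(trials))) ~ lev,
                          FUN = sum)
  level_counts(agg$lev, agg$nc, agg$nt)
}

#' Fit a cumulative-Gaussian psychometric function (2IFC)
#'
#' Bayesian estimation by numerical integration over a dense grid of
#' (location `mu`, slope `sigma`, lapse rate) of the function
#' \deqn{\psi(x) = \gamma + (1 - \gamma - \lambda)\,
#'   \Phi((x - \mu)/\sigma),}
#' with the guess rate fixed at \eqn{\gamma = 0.5} and a binomial
#' likelihood at each dB level. Priors: uniform on `mu` over the tested
#' range (extended by half its span on either side), log-uniform on
#' `sigma` over `sigma_range`, and a `Beta(1, 4)`-shaped prior on the
#' lapse rate over `lapse_range`. Point estimates are posterior means;
#' intervals are central 95% credible intervals. The threshold is the
#' target level at 75% *absolute* correct on the lapse-corrected
#' function, \eqn{\mu + \sigma\,\Phi^{-1}\{(0.75-\gamma)/(1-\gamma-
#' \lambda)\}}, and the equivalent Weibull slope is
#' \eqn{\beta = 10.3/\sigma}.
#'
#' All-correct or all-wrong data are flagged (`identifiable = FALSE`)
#' and return prior-dominated, wide intervals rather than an error.
#'
#' @param counts A [level_counts()] object (>= 2 distinct levels).
#' @param sigma_range Range of sigma (dB) for the log-uniform prior.
#' @param lapse_range Range of the lapse rate.
#' @param grid_n Grid resolution `c(mu, sigma, lapse)`.
#'
#' @return An object of class `psychometric_fit`: `threshold_db`,
#'   `sigma_db`, `beta`, `lapse`, `guess`, `ci_threshold`, `ci_sigma`,
#'   `identifiable`.
#' @export
fit_psychometric <- function(counts, sigma_range = c(0.3, 30),
                             lapse_range = c(0, 0.06),
                             grid_n = c(81L, 41L, 7L)) {
  if (!inherits(counts, "level_counts")) {
    stop("counts must be a level_counts object", call. = FALSE)
  }
  x <- counts$levels_db
  if (length(unique(x)) < 2L) {
    stop("need at least 2 distinct levels", call. = FALSE)
  }
  span <- max(diff(range(x)), 1)
  mu_g <- seq(min(x) - span / 2, max(x) + span / 2,
              length.out = grid_n[1])
  sg_g <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                  length.out = grid_n[2]))
  lp_g <- seq(lapse_range[1], lapse_range[2], length.out = grid_n[3])
  lp_w <- stats::dbeta(
    (lp_g - lapse_range[1]) / max(diff(lapse_range), 1e-9), 1, 4)
  lp_w <- lp_w / sum(lp_w)
  guess <- 0.5

  nl <- length(x)
  # log-likelihood over the (mu, sigma) grid for each lapse value
  ll <- array(0, dim = c(length(mu_g), length(sg_g), length(lp_g)))
  for (il in seq_along(lp_g)) {
    lam <- lp_g[il]
    for (is in seq_along(sg_g)) {
      # matrix: levels x mu
      z <- outer(x, mu_g, "-") / sg_g[is]
      p <- guess + (1 - guess - lam) * stats::pnorm(z)
      p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
      ll[, is, il] <- colSums(counts$n_correct * log(p) +
                                (counts$n_total - counts$n_correct) *
                                log1p(-p))
    }
  }
  lpost <- sweep(ll, 3, log(lp_w), "+")
  lpost <- lpost - max(lpost)
  post <- exp(lpost)
  post <- post / sum(post)

  # derived quantities on the grid
  thr <- array(0, dim = dim(post))
  for (il in seq_along(lp_g)) {
    zq <- stats::qnorm((0.75 - guess) / (1 - guess - lp_g[il]))
    thr[, , il] <- outer(mu_g, sg_g * zq, "+")
  }
  w_thr <- as.numeric(post); v_thr <- as.numeric(thr)
  sg_arr <- array(rep(sg_g, each = length(mu_g)), dim = dim(post))
  v_sg <- as.numeric(sg_arr)

  wq <- function(v, w, probs) {
    o <- order(v)
    cw <- cumsum(w[o])
    stats::approx(cw, v[o], xout = probs, rule = 2, ties = "ordered")$y
  }
  thr_hat <- sum(w_thr * v_thr)
  sg_hat <- sum(w_thr * v_sg)
  ci_thr <- wq(v_thr, w_thr, c(0.025, 0.975))
  ci_sg <- wq(v_sg, w_thr, c(0.025, 0.975))
  lp_hat <- sum(post * array(rep(lp_g, each = length(mu_g) * length(sg_g)),
                             dim = dim(post)))
  degenerate <- all(counts$n_correct == counts$n_total) ||
    all(counts$n_correct == 0L) ||
    all(counts$n_correct * 2L <= counts$n_total)
  structure(list(threshold_db = thr_hat, sigma_db = sg_hat,
                 beta = 10.3 / sg_hat, lapse = lp_hat, guess = guess,
                 ci_threshold = ci_thr, ci_sigma = ci_sg,
                 identifiable = !degenerate,
                 n_trials = sum(counts$n_total)),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "Psychometric fit: threshold %.2f dB [%.2f, %.2f], sigma %.2f dB, beta %.2f%s\n",
    x$threshold_db, x$ci_threshold[1], x$ci_threshold[2], x$sigma_db,
    x$beta, if (x$identifiable) "" else "  (non-identifiable data)"))
  invisible(x)
}

#' Threshold elevation between two psychometric fits
#'
#' The masked-to-baseline threshold ratio on the linear contrast scale,
#' \eqn{10^{(t_{masked} - t_{baseline})/20}}.
#'
#' @param masked,baseline [fit_psychometric()] results.
#' @return A positive factor (1 = no elevation).
#' @export
threshold_elevation <- function(masked, baseline) {
  stopifnot(inherits(masked, "psychometric_fit"),
            inherits(baseline, "psychometric_fit"))
  10^((masked$threshold_db - baseline$threshold_db) / 20)
}
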