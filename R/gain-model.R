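#' Stage-1 monocular response with interocular suppression
#'
#' The first stage of the two-stage model: an accelerating transducer on
#' the driving eye's contrast, divisively normalized by its own contrast
#' and by the other eye's contrast weighted by `omega`:
#' \deqn{Stage1 = C_d^m / (S + C_d + \omega C_o).}
#' Contrasts are in monocular-threshold-normalized linear units. Zero
#' driving contrast returns exactly 0 (handled analytically, no epsilon).
#'
#' @param c_driving Contrast in the driving eye (>= 0); vectorized.
#' @param c_other Contrast in the other eye (>= 0); vectorized.
#' @param params A [gain_params()] object.
#'
#' @return Non-negative response(s), strictly increasing in `c_driving`
#'   and non-increasing in `c_other`.
#' @export
#' @examples
#' p <- example_params("meese2006")
#' stage1_response(1, 0, p)   # ~0.5025
#' stage1_response(1, 1, p)   # ~0.3344
stage1_response <- function(c_driving, c_other, params) {
  validate_gain_params(params)
  check_contrast(c_driving, "c_driving")
  check_contrast(c_other, "c_other")
  out <- ifelse(c_driving <= 0, 0,
                c_driving^params$m /
                  (params$S + c_driving + params$omega * c_other))
  as.numeric(out)
}

check_contrast <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(what, " must be finite and non-negative", call. = FALSE)
  }
  invisible(x)
}

# Stage-2 nonlinearity applied to the binocular sum; binsum == 0 returns 0
# analytically so that Z = 0 parameter sets remain well-defined.
stage2_response <- function(binsum, params) {
  ifelse(binsum <= 0, 0,
         binsum^params$p / (params$Z + binsum^params$q))
}

# Validation-free model response for solver/fitting hot loops.
.resp <- function(L, R, params) {
  s1 <- ifelse(L <= 0, 0, L^params$m / (params$S + L + params$omega * R))
  s2 <- ifelse(R <= 0, 0, R^params$m / (params$S + R + params$omega * L))
  b <- s1 + s2
  ifelse(b <= 0, 0, b^params$p / (params$Z + b^params$q))
}

#' Full model response to a pair of eye contrasts
#'
#' Sums the two stage-1 outputs binocularly and applies the stage-2
#' nonlinearity \eqn{b^p / (Z + b^q)}.
#'
#' @param left,right Contrasts shown to the left and right eyes
#'   (normalized units, >= 0); vectorized in parallel.
#' @inheritParams stage1_response
#'
#' @return Non-negative model response(s); 0 when both contrasts are 0.
#' @export
#' @examples
#' p <- example_params("meese2006")
#' model_response(1, 1, p)
model_response <- function(left, right, params) {
  validate_gain_params(params)
  check_contrast(left, "left")
  check_contrast(right, "right")
  binsum <- stage1_response(left, right, params) +
    stage1_response(right, left, params)
  as.numeric(stage2_response(binsum, params))
}

#' Ocular stimulus arrangements
#'
#' The four classic pedestal-plus-target configurations. `arrangements()`
#' lists the valid tags.
#'
#' @return Character vector of arrangement tags.
#' @export
arrangements <- function() {
  c("monocular", "binocular", "half_binocular", "dichoptic")
}

#' Map pedestal and target contrasts to per-eye contrasts
#'
#' Computes the eye contrasts of the target interval and the null interval
#' of a 2IFC trial for a given ocular arrangement. With the target in the
#' left eye the mappings (target interval / null interval) are:
#' monocular `(P+T, 0) / (P, 0)`; binocular `(P+T, P+T) / (P, P)`;
#' half-binocular `(P+T, P) / (P, P)`; dichoptic `(T, P) / (0, P)`.
#' `target_eye = "right"` swaps the left/right roles.
#'
#' @param pedestal Pedestal contrast (normalized units, >= 0).
#' @param target Target increment contrast (normalized units, >= 0).
#' @param arrangement One of [arrangements()].
#' @param target_eye `"left"` or `"right"`.
#'
#' @return A list with elements `target` and `null`, each a named numeric
#'   vector `c(left = , right = )`.
#' @export
#' @examples
#' arrange_contrasts(8, 2, "dichoptic")  # target (2, 8), null (0, 8)
arrange_contrasts <- function(pedestal, target, arrangement,
                              target_eye = c("left", "right")) {
  target_eye <- match.arg(target_eye)
  check_contrast(pedestal, "pedestal")
  check_contrast(target, "target")
  P <- pedestal; T <- target
  out <- switch(arrangement,
    monocular      = list(target = c(P + T, 0),     null = c(P, 0)),
    binocular      = list(target = c(P + T, P + T), null = c(P, P)),
    half_binocular = list(target = c(P + T, P),     null = c(P, P)),
    dichoptic      = list(target = c(T, P),         null = c(0, P)),
    stop("unknown arrangement '", arrangement, "'", call. = FALSE)
  )
  if (target_eye == "right") out <- lapply(out, rev)
  lapply(out, function(v) stats::setNames(v, c("left", "right")))
}

# Response difference between target and null intervals, vectorized
# elementwise over `target` and `pedestal` (recycled). This is the
# quantity compared against k at threshold. The model response is
# symmetric in the two eyes, so the target_eye label never changes this
# value; the eye-contrast mapping is inlined (rather than via
# arrange_contrasts) because threshold solving and simplex fitting
# evaluate it millions of times.
response_difference <- function(target, pedestal, arrangement, params,
                                target_eye = "left") {
  n <- max(length(target), length(pedestal))
  if (n == 0L) return(numeric(0))
  P <- rep_len(pedestal, n); T <- rep_len(target, n)
  z <- numeric(n)
  eyes <- switch(arrangement,
    monocular      = list(tl = P + T, tr = z,     nl = P, nr = z),
    binocular      = list(tl = P + T, tr = P + T, nl = P, nr = P),
    half_binocular = list(tl = P + T, tr = P,     nl = P, nr = P),
    dichoptic      = list(tl = T,     tr = P,     nl = z, nr = P),
    stop("unknown arrangement '", arrangement, "'", call. = FALSE)
  )
  .resp(eyes$tl, eyes$tr, params) - .resp(eyes$nl, eyes$nr, params)
}

#' Model d-prime for a target on a pedestal
#'
#' Converts the response difference between the target and null intervals
#' to sensitivity: \eqn{d' = (R_{target} - R_{null}) / (k/\tau)}. At the
#' threshold target contrast this equals `tau` (0.954) by construction.
#' d-prime can be negative for dichoptic arrangements at small targets on
#' large pedestals (the "swan" region), because a weak target suppresses
#' the other eye's pedestal response more than it adds excitation.
#'
#' @param target Target contrast(s) (normalized units, >= 0); vectorized.
#' @inheritParams arrange_contrasts
#' @inheritParams stage1_response
#'
#' @return d-prime value(s); 0 when `target` is 0.
#' @export
#' @examples
#' p <- example_params("meese2006")
#' dprime(0.5, 16, "dichoptic", p)  # negative: swan region
dprime <- function(target, pedestal, arrangement, params,
                   target_eye = "left") {
  validate_gain_params(params)
  response_difference(target, pedestal, arrangement, params, target_eye) /
    (params$k / params$tau)
}

#' Solve for the discrimination threshold on a pedestal
#'
#' Finds the smallest target contrast at which the model response
#' difference between target and null intervals equals `k` (equivalently,
#' d-prime equals `tau`). A log-spaced grid over `bracket` is scanned for
#' the first upward crossing of (response difference - k) — dichoptic
#' response differences are non-monotonic, so the first crossing matters —
#' followed by bisection in log contrast. Vectorized over `pedestal`.
#'
#' @param pedestal Pedestal contrast(s) (normalized units, >= 0).
#' @inheritParams arrange_contrasts
#' @inheritParams stage1_response
#' @param tol Relative tolerance on the threshold criterion: the returned
#'   target satisfies |response difference - k| <= `tol * k`.
#' @param bracket Search range for the target contrast (normalized units).
#' @param grid_n Number of log-spaced scan points across `bracket`.
#'
#' @return Threshold contrast(s) in normalized units. Throws an error if
#'   no crossing exists within `bracket` (never silently clamped).
#' @export
#' @examples
#' p <- example_params("meese2006")
#' solve_threshold(0, "monocular", p)  # ~1.348
solve_threshold <- function(pedestal, arrangement, params,
                            target_eye = "left", tol = 1e-6,
                            bracket = c(1e-4, 1e4), grid_n = 64L) {
  validate_gain_params(params)
  check_contrast(pedestal, "pedestal")
  np <- length(pedestal)
  if (np == 0L) return(numeric(0))
  k <- params$k
  lg <- seq(log(bracket[1]), log(bracket[2]), length.out = grid_n)

  # grid scan: one vectorized model evaluation over (target x pedestal)
  f <- response_difference(rep(exp(lg), np),
                           rep(pedestal, each = grid_n),
                           arrangement, params, target_eye) - k
  dim(f) <- c(grid_n, np)
  lo <- numeric(np); hi <- numeric(np)
  for (j in seq_len(np)) {
    ix <- which(f[, j] > 0)
    if (length(ix) == 0L || ix[1] == 1L) {
      stop("solve_threshold: no sign change within the search bracket for ",
           "pedestal ", pedestal[j], " (", arrangement, ")", call. = FALSE)
    }
    lo[j] <- lg[ix[1] - 1L]; hi[j] <- lg[ix[1]]
  }
  # bisection on the log-contrast axis, vectorized across pedestals;
  # depth scales with the requested tolerance
  width_stop <- max(tol * 1e-2, 1e-12)
  for (it in seq_len(50L)) {
    mid <- (lo + hi) / 2
    up <- response_difference(exp(mid), pedestal, arrangement, params,
                              target_eye) > k
    hi[up] <- mid[up]; lo[!up] <- mid[!up]
    if (max(hi - lo) < width_stop) break
  }
  th <- exp((lo + hi) / 2)
  err <- abs(response_difference(th, pedestal, arrangement, params,
                                 target_eye) - k)
  if (any(err > tol * k)) {
    stop("solve_threshold: criterion not met to tolerance (max relative ",
         "error ", signif(max(err) / k, 3), ")", call. = FALSE)
  }
  th
}

#' Generate a dipper function (threshold versus pedestal contrast)
#'
#' Solves the discrimination threshold at each pedestal for one ocular
#' arrangement, producing the classic dipper curve: facilitation at
#' near-threshold pedestals, masking at high pedestals.
#'
#' @param pedestals Pedestal contrasts, sorted ascending (normalized
#'   units, >= 0).
#' @inheritParams solve_threshold
#'
#' @return A tibble of class `dipper_curve` with columns `pedestal_norm`
#'   and `threshold_norm`, and attributes `arrangement` and `target_eye`.
#' @export
#' @examples
#' p <- example_params("meese2006")
#' dipper_curve(c(0, 0.5, 1, 2, 4, 8, 16, 32), "binocular", p)
dipper_curve <- function(pedestals, arrangement, params,
                         target_eye = "left", tol = 1e-6) {
  if (is.unsorted(pedestals, strictly = TRUE)) {
    stop("pedestals must be strictly increasing", call. = FALSE)
  }
  th <- solve_threshold(pedestals, arrangement, params,
                        target_eye = target_eye, tol = tol)
  out <- tibble::tibble(pedestal_norm = as.numeric(pedestals),
                        threshold_norm = as.numeric(th))
  structure(out, arrangement = arrangement, target_eye = target_eye,
            class = c("dipper_curve", class(out)))
}

#' Summary statistics of a dipper function
#'
#' Computes the facilitation factor (zero-pedestal threshold divided by
#' the minimum threshold over pedestals), the handle slope (ordinary
#' least-squares slope of dB threshold against dB pedestal over the
#' highest four pedestals; the zero pedestal is never included), and —
#' when a monocular reference curve is supplied — the binocular summation
#' ratio (monocular / binocular zero-pedestal threshold, approximately
#' \eqn{2^{1/m}} in the low-contrast limit).
#'
#' @param curve A [dipper_curve()] (typically binocular or dichoptic).
#' @param ref_curve Optional reference [dipper_curve()] (typically
#'   monocular) sharing the zero pedestal; needed for `summation_ratio`.
#'
#' @return A list with `summation_ratio` (or `NA`), `facilitation_factor`
#'   and `handle_slope`.
#' @export
summarize_dipper <- function(curve, ref_curve = NULL) {
  if (!any(curve$pedestal_norm == 0)) {
    stop("curve must include a zero-pedestal (detection) point",
         call. = FALSE)
  }
  th0 <- curve$threshold_norm[curve$pedestal_norm == 0][1]
  nz <- curve[curve$pedestal_norm > 0, ]
  if (nrow(nz) < 4L) {
    stop("handle slope requires at least 4 nonzero pedestals",
         call. = FALSE)
  }
  top <- nz[order(nz$pedestal_norm, decreasing = TRUE)[1:4], ]
  x <- 20 * log10(top$pedestal_norm)
  y <- 20 * log10(top$threshold_norm)
  slope <- unname(stats::coef(stats::lm(y ~ x))[2])
  ratio <- NA_real_
  if (!is.null(ref_curve)) {
    if (!any(ref_curve$pedestal_norm == 0)) {
      stop("ref_curve must include a zero-pedestal point", call. = FALSE)
    }
    r0 <- ref_curve$threshold_norm[ref_curve$pedestal_norm == 0][1]
    ratio <- r0 / th0
  }
  list(summation_ratio = ratio,
       facilitation_factor = th0 / min(curve$threshold_norm),
       handle_slope = slope)
}
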