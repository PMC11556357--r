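#' Labels of the three post-retinal pathways
#'
#' `"AC"` (achromatic / luminance), `"RG"` (L-M, red/green) and `"BY"`
#' (S-(L+M), blue/yellow).
#'
#' @return Character vector of pathway labels.
#' @export
pathways <- function() c("AC", "RG", "BY")

#' Cross-pathway binocular gain control model
#'
#' Extends the two-stage model to three parallel mechanisms (achromatic,
#' L-M, S-(L+M)) that suppress each other interocularly at stage 1. For
#' the mechanism tuned to pathway `i`, the left-eye stage-1 response is
#' \deqn{Stage1_{i,L} = C_{i,L}^m / (S + C_{i,L} + \sum_j W_{ij} C_{j,R}),}
#' where the sum runs over all three pathways' right-eye contrasts and
#' \eqn{W} is the 3x3 matrix of interocular suppression weights. The
#' diagonal of \eqn{W} holds the within-pathway weights (each mechanism's
#' own `omega`); off-diagonal entries are the cross-pathway weights. There
#' is no monocular (same-eye) suppression between pathways. Stage 2 is
#' applied per mechanism with that mechanism's `p`, `q` and `Z`.
#'
#' Each pathway's contrasts are in that pathway's own
#' monocular-threshold-normalized units.
#'
#' @param mechanisms Named list (`AC`, `RG`, `BY`) of [gain_params()]: the
#'   per-mechanism `p`, `q`, `m`, `S`, `Z`, `omega`, `k`. The within-pathway
#'   weights on the diagonal of the suppression matrix are taken from each
#'   mechanism's `omega`.
#' @param cross_weights 3x3 numeric matrix `W[target_pathway,
#'   masking_pathway]` of interocular suppression weights (>= 0).
#'   Diagonal entries are overwritten from `mechanisms` so the
#'   within-pathway weights cannot drift out of step; only the six
#'   off-diagonal entries are free.
#'
#' @return An object of class `crosspath_model`.
#' @seealso [default_crosspath_model()]
#' @export
crosspath_model <- function(mechanisms, cross_weights) {
  if (!identical(sort(names(mechanisms)), sort(pathways()))) {
    stop("mechanisms must be a named list with elements AC, RG, BY",
         call. = FALSE)
  }
  for (pw in pathways()) validate_gain_params(mechanisms[[pw]])
  W <- as.matrix(cross_weights)
  if (!all(dim(W) == c(3L, 3L)) || any(!is.finite(W)) || any(W < 0)) {
    stop("cross_weights must be a finite non-negative 3x3 matrix",
         call. = FALSE)
  }
  dimnames(W) <- list(pathways(), pathways())
  diag(W) <- vapply(pathways(), function(pw) mechanisms[[pw]]$omega,
                    numeric(1))
  structure(list(mechanisms = mechanisms[pathways()], weights = W),
            class = "crosspath_model")
}

#' @export
print.crosspath_model <- function(x, ...) {
  cat("Cross-pathway binocular gain control model\n")
  cat("Interocular suppression weights W[target, mask]:\n")
  print(round(x$weights, 3))
  invisible(x)
}

#' Default cross-pathway model
#'
#' Mechanism parameters are the hierarchical-Bayesian (MAP) estimates for
#' the three grating pathways (see [example_params()]). The cross-pathway
#' weights follow the fitted pattern: strongest suppression of the L-M
#' mechanism by the S-(L+M) mask (weight 1.11), weakest coupling between
#' the achromatic and S-(L+M) pathways, intermediate elsewhere.
#'
#' @return A [crosspath_model()] object.
#' @export
default_crosspath_model <- function() {
  mech <- list(AC = example_params("bayes_achromatic"),
               RG = example_params("bayes_lm"),
               BY = example_params("bayes_s"))
  W <- matrix(c(NA,   0.50, 0.30,
                0.50, NA,   1.11,
                0.30, 0.80, NA), nrow = 3, byrow = TRUE,
              dimnames = list(pathways(), pathways()))
  W[is.na(W)] <- 0  # diagonal filled from mechanism omegas by constructor
  crosspath_model(mech, W)
}

# contrasts: list(left = c(AC=,RG=,BY=), right = c(AC=,RG=,BY=))
.check_pathway <- function(pathway) {
  if (!pathway %in% pathways()) {
    stop("pathway must be one of ", paste(pathways(), collapse = ", "),
         call. = FALSE)
  }
  pathway
}

#' Stage-1 response of one mechanism in one eye
#'
#' @param model A [crosspath_model()].
#' @param left,right Named numeric vectors of per-pathway contrasts
#'   (`AC`, `RG`, `BY`) for the two eyes, each in its own pathway's
#'   normalized units.
#' @param pathway Which mechanism (`"AC"`, `"RG"`, `"BY"`).
#' @param eye Which eye's response (`"left"` or `"right"`).
#'
#' @return Non-negative stage-1 response of that mechanism in that eye.
#' @export
#' @examples
#' m <- default_crosspath_model()
#' crosspath_stage1(m, left = c(AC = 1, RG = 0, BY = 0),
#'                  right = c(AC = 0, RG = 0, BY = 16), pathway = "AC")
crosspath_stage1 <- function(model, left, right, pathway,
                             eye = c("left", "right")) {
  eye <- match.arg(eye)
  .check_pathway(pathway)
  left <- left[pathways()]; right <- right[pathways()]
  check_contrast(unname(left), "left"); check_contrast(unname(right), "right")
  own <- if (eye == "left") left else right
  other <- if (eye == "left") right else left
  par <- model$mechanisms[[pathway]]
  cd <- own[[pathway]]
  if (cd <= 0) return(0)
  sup <- sum(model$weights[pathway, ] * other)
  unname(cd^par$m / (par$S + cd + sup))
}

# Stage-2 response of the mechanism tuned to `pathway`, given full
# per-pathway eye contrasts. Within-pathway dichoptic masks enter the
# excitatory path of the other eye automatically; cross-pathway masks
# contribute only suppressive denominator terms.
mechanism_response <- function(model, left, right, pathway) {
  par <- model$mechanisms[[pathway]]
  b <- crosspath_stage1(model, left, right, pathway, "left") +
    crosspath_stage1(model, left, right, pathway, "right")
  as.numeric(stage2_response(b, par))
}

#' Define a dichoptic masking condition
#'
#' A target in one pathway shown to one eye, with an optional mask in any
#' pathway shown to the other eye (the factorial design of a
#' cross-pathway dichoptic masking experiment: 3 baselines + 9 target x
#' mask pairings). Target and mask never share an eye.
#'
#' @param target_pathway Pathway of the target (`"AC"`, `"RG"`, `"BY"`).
#' @param mask_pathway Pathway of the mask, or `"none"` for baseline
#'   detection.
#' @param mask_contrast Mask contrast in the mask pathway's normalized
#'   units (ignored when `mask_pathway = "none"`); the classic design puts
#'   this at about 16 times the monocular detection threshold.
#' @param target_eye Eye receiving the target; the mask goes to the other.
#'
#' @return An object of class `masking_condition`.
#' @export
masking_condition <- function(target_pathway,
                              mask_pathway = "none",
                              mask_contrast = 16,
                              target_eye = c("left", "right")) {
  target_eye <- match.arg(target_eye)
  .check_pathway(target_pathway)
  if (!identical(mask_pathway, "none")) .check_pathway(mask_pathway)
  if (identical(mask_pathway, "none")) mask_contrast <- 0
  check_contrast(mask_contrast, "mask_contrast")
  structure(list(target_pathway = target_pathway,
                 mask_pathway = mask_pathway,
                 mask_contrast = mask_contrast,
                 target_eye = target_eye),
            class = "masking_condition")
}

# Per-pathway eye contrasts of the target and null intervals for a
# masking condition at a given target contrast.
crosspath_contrasts <- function(cond, target) {
  zero <- stats::setNames(numeric(3), pathways())
  tgt_eye <- zero; msk_eye <- zero
  tgt_eye[cond$target_pathway] <- target
  if (!identical(cond$mask_pathway, "none")) {
    msk_eye[cond$mask_pathway] <- cond$mask_contrast
  }
  if (cond$target_eye == "left") {
    list(target = list(left = tgt_eye, right = msk_eye),
         null   = list(left = zero,    right = msk_eye))
  } else {
    list(target = list(left = msk_eye, right = tgt_eye),
         null   = list(left = msk_eye, right = zero))
  }
}

#' d-prime in a cross-pathway masking condition
#'
#' Reads out the mechanism tuned to the target's pathway (the observer
#' always knows the target identity) and converts its response difference
#' between the target-plus-mask and mask-only displays to d-prime using
#' that mechanism's `k` and `tau`. Within-pathway dichoptic masks can
#' produce negative d-prime at small target contrasts (swan region).
#'
#' @param cond A [masking_condition()].
#' @param target Target contrast(s), normalized units; vectorized.
#' @param model A [crosspath_model()].
#'
#' @return d-prime value(s).
#' @export
crosspath_dprime <- function(cond, target, model) {
  if (!inherits(cond, "masking_condition")) {
    stop("cond must be a masking_condition", call. = FALSE)
  }
  check_contrast(target, "target")
  par <- model$mechanisms[[cond$target_pathway]]
  vapply(target, function(tt) {
    cc <- crosspath_contrasts(cond, tt)
    rt <- mechanism_response(model, cc$target$left, cc$target$right,
                             cond$target_pathway)
    rn <- mechanism_response(model, cc$null$left, cc$null$right,
                             cond$target_pathway)
    (rt - rn) / (par$k / par$tau)
  }, numeric(1))
}

#' Convert d-prime to 2IFC percent correct
#'
#' The standard two-alternative signal-detection link,
#' \eqn{P = \lambda/2 + (1-\lambda)\Phi(d'/\sqrt{2})}, with lapse rate
#' `lapse`. At d-prime = `tau_2ifc()` this gives 75% correct when
#' `lapse = 0`; negative d-prime yields below-chance performance (the swan
#' region).
#'
#' @param dp d-prime value(s).
#' @param lapse Lapse rate in `[0, 1]`.
#'
#' @return Probability correct in `[lapse/2, 1 - lapse/2]`.
#' @export
dprime_to_pc <- function(dp, lapse = 0) {
  if (lapse < 0 || lapse > 1) stop("lapse must be in [0, 1]", call. = FALSE)
  lapse / 2 + (1 - lapse) * stats::pnorm(dp / sqrt(2))
}

#' Model psychometric function for a masking condition
#'
#' Percent correct at each target level via [crosspath_dprime()] and the
#' 2IFC link [dprime_to_pc()]. Values below 50% are permitted (swan
#' functions under strong within-pathway dichoptic masking).
#'
#' @inheritParams crosspath_dprime
#' @param target_levels Target contrasts (> 0), normalized units.
#' @param lapse Lapse rate passed to [dprime_to_pc()].
#'
#' @return Numeric vector of probabilities correct, one per level.
#' @export
predict_psychometric <- function(cond, target_levels, model, lapse = 0.01) {
  if (any(target_levels <= 0)) {
    stop("target_levels must be > 0", call. = FALSE)
  }
  dprime_to_pc(crosspath_dprime(cond, target_levels, model), lapse)
}

#' Solve the 75%-correct threshold in a masking condition
#'
#' Smallest target contrast at which the target mechanism's d-prime
#' reaches `tau` (the 75% point of the lapse-free psychometric function).
#' Same first-upward-crossing grid + bisection scheme as
#' [solve_threshold()].
#'
#' @inheritParams crosspath_dprime
#' @param tol Relative tolerance on d-prime at the returned threshold.
#' @param bracket,grid_n Search grid over target contrast.
#'
#' @return Threshold contrast in normalized units.
#' @export
crosspath_threshold <- function(cond, model, tol = 1e-6,
                                bracket = c(1e-4, 1e4), grid_n = 64L) {
  par <- model$mechanisms[[cond$target_pathway]]
  tau <- par$tau
  lg <- seq(log(bracket[1]), log(bracket[2]), length.out = grid_n)
  f <- crosspath_dprime(cond, exp(lg), model) - tau
  ix <- which(f > 0)
  if (length(ix) == 0L || ix[1] == 1L) {
    stop("crosspath_threshold: no crossing within the search bracket",
         call. = FALSE)
  }
  lo <- lg[ix[1] - 1L]; hi <- lg[ix[1]]
  for (it in seq_len(60L)) {
    mid <- (lo + hi) / 2
    if (crosspath_dprime(cond, exp(mid), model) - tau > 0) hi <- mid
    else lo <- mid
    if (hi - lo < 1e-12) break
  }
  th <- exp((lo + hi) / 2)
  if (abs(crosspath_dprime(cond, th, model) - tau) > tol * tau) {
    stop("crosspath_threshold: criterion not met to tolerance",
         call. = FALSE)
  }
  th
}
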