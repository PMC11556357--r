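#' d-prime at a 75%-correct 2IFC detection threshold
#'
#' The sensitivity that corresponds to 75% correct performance in a
#' two-interval forced-choice task: \eqn{\tau = \Phi^{-1}(0.75)\sqrt{2}
#' \approx 0.954}. The model converts response differences to d-prime by
#' dividing by \eqn{k/\tau}, so that a response difference of exactly `k`
#' sits at detection threshold.
#'
#' @return A single number, approximately 0.954.
#' @export
#' @examples
#' tau_2ifc()
tau_2ifc <- function() {
  stats::qnorm(0.75) * sqrt(2)
}

#' Parameters of the two-stage binocular gain control model
#'
#' Bundles the seven free parameters of the two-stage model together with
#' the fixed threshold d-prime constant `tau`. Stage 1 applies interocular
#' suppression before binocular summation,
#' \deqn{Stage1_L = C_L^m / (S + C_L + \omega C_R),}
#' and stage 2 applies a second nonlinearity to the binocular sum
#' \eqn{b = Stage1_L + Stage1_R}:
#' \deqn{Stage2 = b^p / (Z + b^q).}
#' The parameter `k` is the response difference at detection threshold and
#' doubles (as \eqn{k/\tau}) as the internal additive noise standard
#' deviation.
#'
#' @param p Stage-2 numerator exponent (> 0).
#' @param q Stage-2 denominator exponent (> 0).
#' @param m Stage-1 excitatory exponent (> 0); controls binocular summation
#'   at threshold (ratio approximately \eqn{2^{1/m}} in the low-contrast
#'   limit).
#' @param S Stage-1 saturation constant, in monocular-threshold-normalized
#'   contrast units (> 0).
#' @param Z Stage-2 saturation constant (>= 0).
#' @param omega Weight of interocular suppression (>= 0); a value near 1
#'   produces ocularity invariance and the convergence of monocular and
#'   binocular dipper handles.
#' @param k Response-difference criterion at threshold (> 0).
#' @param tau d-prime at detection threshold; fixed at
#'   \eqn{\Phi^{-1}(0.75)\sqrt{2}} unless explicitly overridden.
#'
#' @return An object of class `gain_params` (a named list).
#' @seealso [example_params()] for published parameter sets.
#' @export
#' @examples
#' gain_params(p = 7.99, q = 6.59, m = 1.28, S = 0.99, Z = 0.08,
#'             omega = 1.00, k = 0.19)
gain_params <- function(p, q, m, S, Z, omega, k, tau = tau_2ifc()) {
  par <- list(p = p, q = q, m = m, S = S, Z = Z, omega = omega, k = k,
              tau = tau)
  validate_gain_params(par)
  structure(par, class = "gain_params")
}

validate_gain_params <- function(par) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("p", "q", "m", "S", "Z", "omega", "k", "tau")) {
    if (!num1(par[[nm]])) {
      stop("gain_params: '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  if (par$m <= 0 || par$p <= 0 || par$q <= 0 || par$S <= 0 || par$k <= 0) {
    stop("gain_params: m, p, q, S and k must all be > 0", call. = FALSE)
  }
  if (par$Z < 0 || par$omega < 0) {
    stop("gain_params: Z and omega must be >= 0", call. = FALSE)
  }
  invisible(par)
}

#' @export
print.gain_params <- function(x, ...) {
  cat("Two-stage binocular gain control parameters\n")
  v <- unlist(x[c("p", "q", "m", "S", "Z", "omega", "k", "tau")])
  print(round(v, 4))
  invisible(x)
}

#' Published and representative parameter sets for the two-stage model
#'
#' Named parameter sets for the two-stage model: the classic achromatic
#' estimates of Meese, Georgeson and Baker (2006), together with
#' representative simplex and Bayesian (MAP) estimates for achromatic
#' gratings, the two isoluminant chromatic pathways (L-M, S-(L+M)) and a
#' 4 Hz flickering disc. These serve as generating parameters for the
#' synthetic observer and as starting references for model fitting.
#'
#' @param set Name of the parameter set; see `names(example_params())`.
#'   With `set = NULL` (default) the full named list is returned.
#'
#' @return A `gain_params` object, or a named list of them.
#' @export
#' @examples
#' example_params("meese2006")
example_params <- function(set = NULL) {
  tab <- list(
    meese2006          = c(7.99,  6.59,  1.28, 0.99, 0.08, 1.00, 0.19),
    achromatic_grating = c(5.96,  4.69,  1.34, 0.87, 0.13, 1.00, 0.20),
    lm_grating         = c(7.77,  5.19,  1.17, 0.55, 0.07, 1.00, 0.17),
    s_grating          = c(16.01, 11.56, 1.13, 0.33, 0.00, 0.99, 0.27),
    flicker_disc       = c(5.62,  4.51,  1.26, 0.95, 0.25, 0.89, 0.13),
    bayes_achromatic   = c(7.06,  5.63,  1.27, 0.63, 0.08, 0.98, 0.30),
    bayes_lm           = c(5.11,  3.63,  1.24, 1.22, 0.03, 1.05, 0.19),
    bayes_s            = c(6.78,  5.34,  1.24, 0.61, 0.01, 0.95, 0.34),
    bayes_flicker      = c(7.16,  5.76,  1.25, 0.65, 0.13, 0.87, 0.24)
  )
  mk <- function(v) gain_params(p = v[1], q = v[2], m = v[3], S = v[4],
                                Z = max(v[5], 0), omega = v[6], k = v[7])
  out <- lapply(tab, mk)
  if (is.null(set)) return(out)
  if (!set %in% names(out)) {
    stop("unknown parameter set '", set, "'; available: ",
         paste(names(out), collapse = ", "), call. = FALSE)
  }
  out[[set]]
}
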