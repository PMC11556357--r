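#' Root-mean-squared error between thresholds in dB
#'
#' @param model_thresholds,data_thresholds Positive thresholds (linear
#'   normalized units), equal length.
#' @return RMSE of the difference of `20*log10` values, in dB.
#' @export
rmse_dB <- function(model_thresholds, data_thresholds) {
  if (length(model_thresholds) != length(data_thresholds)) {
    stop("threshold vectors must have equal length", call. = FALSE)
  }
  if (any(model_thresholds <= 0) || any(data_thresholds <= 0)) {
    stop("thresholds must be positive", call. = FALSE)
  }
  d <- 20 * log10(model_thresholds) - 20 * log10(data_thresholds)
  sqrt(mean(d^2))
}

# Accept a dipper_curve, a list of them, or a plain table with columns
# arrangement / pedestal_norm / threshold_norm.
as_threshold_table <- function(x) {
  if (inherits(x, "dipper_curve")) {
    out <- tibble::tibble(arrangement = attr(x, "arrangement"),
                          pedestal_norm = x$pedestal_norm,
                          threshold_norm = x$threshold_norm)
    return(out)
  }
  if (is.list(x) && !is.data.frame(x) &&
      all(vapply(x, inherits, logical(1), "dipper_curve"))) {
    return(do.call(rbind, lapply(x, as_threshold_table)))
  }
  need <- c("arrangement", "pedestal_norm", "threshold_norm")
  if (is.data.frame(x) && all(need %in% names(x))) {
    return(tibble::as_tibble(x[, need]))
  }
  stop("cannot interpret threshold data; supply dipper_curve(s) or a ",
       "table with arrangement/pedestal_norm/threshold_norm", call. = FALSE)
}

# Log-uniform start ranges for the free parameters (also the bounds used
# to draw simplex starting vectors).
param_start_ranges <- function() {
  list(p = c(2, 16), q = c(2, 14), m = c(0.8, 2), S = c(0.1, 3),
       Z = c(0.005, 1), omega = c(0.2, 2), k = c(0.02, 1))
}

model_thresholds_for <- function(params, data) {
  out <- numeric(nrow(data))
  for (arr in unique(data$arrangement)) {
    ix <- which(data$arrangement == arr)
    o <- order(data$pedestal_norm[ix])
    out[ix[o]] <- solve_threshold(sort(data$pedestal_norm[ix]), arr,
                                  params, tol = 1e-4)
  }
  out
}

#' Multi-start simplex fit of the two-stage model to threshold data
#'
#' Minimizes the dB RMSE between model and data thresholds over a subset
#' of free parameters using Nelder-Mead simplex, restarted from
#' `n_starts` random starting vectors (log-uniform within the ranges of
#' `param_start_ranges()`); the best solution is returned. Free
#' parameters are optimized on the log scale, which enforces positivity.
#' Ties between equal-RMSE starts are broken by the lowest start index.
#'
#' @param data Threshold data: a [dipper_curve()], a list of them, or a
#'   table with columns `arrangement`, `pedestal_norm`, `threshold_norm`.
#' @param free Character vector naming the free parameters (subset of
#'   p, q, m, S, Z, omega, k).
#' @param params A [gain_params()] supplying the fixed parameters (and
#'   initial values of the free ones).
#' @param n_starts Number of random starting vectors (default 100).
#' @param seed Optional integer seed; the fit is deterministic given it.
#' @param maxit Maximum simplex iterations per start.
#'
#' @return An object of class `gain_fit`: `params` (best-fitting
#'   [gain_params()]), `rmse_db`, `n_starts`, `best_start`, `free`,
#'   `convergence`.
#' @export
simplex_fit <- function(data, free, params, n_starts = 100L, seed = NULL,
                        maxit = 500L) {
  data <- as_threshold_table(data)
  if (nrow(data) == 0L) stop("no threshold data", call. = FALSE)
  validate_gain_params(params)
  rng <- param_start_ranges()
  if (!all(free %in% names(rng))) {
    stop("free must be a subset of ", paste(names(rng), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  objective <- function(logpar) {
    cand <- params
    cand[free] <- as.list(exp(logpar))
    th <- tryCatch(model_thresholds_for(cand, data),
                   error = function(e) NULL)
    if (is.null(th)) return(1e3)
    rmse_dB(th, data$threshold_norm)
  }

  nf <- length(free)
  starts <- matrix(0, nrow = n_starts, ncol = nf)
  for (j in seq_len(nf)) {
    r <- rng[[free[j]]]
    starts[, j] <- stats::runif(n_starts, log(r[1]), log(r[2]))
  }
  best <- NULL; best_val <- Inf; best_start <- NA_integer_
  for (i in seq_len(n_starts)) {
    fit <- suppressWarnings(
      stats::optim(starts[i, ], objective, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-9)))
    if (fit$value < best_val - 1e-12) {
      best <- fit; best_val <- fit$value; best_start <- i
    }
  }
  if (is.null(best) || !is.finite(best_val) || best_val >= 1e3) {
    stop("simplex_fit: all starts failed (no valid threshold solution)",
         call. = FALSE)
  }
  out_par <- params
  out_par[free] <- as.list(exp(best$par))
  out_par <- do.call(gain_params, out_par[c("p", "q", "m", "S", "Z",
                                            "omega", "k", "tau")])
  structure(list(params = out_par, rmse_db = best_val,
                 n_starts = as.integer(n_starts),
                 best_start = best_start, free = free,
                 convergence = best$convergence),
            class = "gain_fit")
}

#' @export
print.gain_fit <- function(x, ...) {
  cat(sprintf("Simplex fit (%d starts, best %d): RMSE %.4f dB\n",
              x$n_starts, x$best_start, x$rmse_db))
  cat("Free:", paste(x$free, collapse = ", "), "\n")
  print(x$params)
  invisible(x)
}

#' Priors for the hierarchical Bayesian model fit
#'
#' Gaussian priors on `p`, `q`, `m` and `omega` centred on the classic
#' published estimates, uniform priors on `S`, `Z` and `k`, and a
#' uniform prior on the log-scale SD of the participant-level
#' parameters.
#'
#' @param p,q,m,omega `c(mean, sd)` of the Gaussian priors.
#' @param S,Z,k `c(lower, upper)` of the uniform priors.
#' @param subject_sd `c(lower, upper)` of the participant-level log SD.
#' @export
default_priors <- function(p = c(7.99, 2), q = c(6.59, 2),
                           m = c(1.28, 0.3), omega = c(1.00, 0.3),
                           S = c(0.001, 3), Z = c(1e-4, 1),
                           k = c(0.001, 2), subject_sd = c(0.01, 0.5)) {
  list(p = p, q = q, m = m, omega = omega, S = S, Z = Z, k = k,
       subject_sd = subject_sd)
}

#' MCMC configuration
#'
#' @param n_chains Number of chains.
#' @param n_adapt Adaptation iterations.
#' @param n_burnin Burn-in iterations discarded after adaptation.
#' @param n_iter Sampling iterations per chain.
#' @param retain_fraction Fraction of draws retained in `samples`
#'   (thinning; default 10%). Summaries use the retained draws.
#' @export
mcmc_config <- function(n_chains = 2L, n_adapt = 500L, n_burnin = 500L,
                        n_iter = 2000L, retain_fraction = 0.1) {
  list(n_chains = as.integer(n_chains), n_adapt = as.integer(n_adapt),
       n_burnin = as.integer(n_burnin), n_iter = as.integer(n_iter),
       retain_fraction = retain_fraction)
}

# Aggregate a single-pathway trial table into binomial cells with the
# per-eye contrasts of both 2IFC intervals.
trials_to_cells <- function(trials) {
  key <- interaction(trials$participant, trials$arrangement,
                     trials$pedestal_norm, signif(trials$target_norm, 8),
                     drop = TRUE)
  idx <- split(seq_len(nrow(trials)), key)
  n <- length(idx)
  sub <- character(n); tL <- tR <- nL <- nR <- r <- nt <- numeric(n)
  for (i in seq_len(n)) {
    rows <- idx[[i]]
    tr <- trials[rows[1], ]
    a <- arrange_contrasts(tr$pedestal_norm, tr$target_norm,
                           tr$arrangement)
    sub[i] <- tr$participant
    tL[i] <- a$target[["left"]]; tR[i] <- a$target[["right"]]
    nL[i] <- a$null[["left"]]; nR[i] <- a$null[["right"]]
    r[i] <- sum(trials$correct[rows]); nt[i] <- length(rows)
  }
  list(sub = as.integer(factor(sub)), n_sub = length(unique(sub)),
       tL = tL, tR = tR, nL = nL, nR = nR, r = r, n = nt, n_cells = n)
}

gain_jags_model <- function(priors, lapse) {
  sprintf("model {
  pg ~ dnorm(%g, %g) T(0.5,)
  qg ~ dnorm(%g, %g) T(0.5,)
  mg ~ dnorm(%g, %g) T(0.25,)
  wg ~ dnorm(%g, %g) T(0,)
  S ~ dunif(%g, %g)
  Z ~ dunif(%g, %g)
  kg ~ dunif(%g, %g)
  sdm ~ dunif(%g, %g)
  sdw ~ dunif(%g, %g)
  sdk ~ dunif(%g, %g)
  for (s in 1:nsub) {
    m[s] ~ dlnorm(log(mg), 1 / (sdm * sdm))
    w[s] ~ dlnorm(log(wg), 1 / (sdw * sdw))
    k[s] ~ dlnorm(log(kg), 1 / (sdk * sdk))
  }
  for (i in 1:N) {
    s1a[i] <- pow(tL[i], m[sub[i]]) / (S + tL[i] + w[sub[i]] * tR[i])
    s1b[i] <- pow(tR[i], m[sub[i]]) / (S + tR[i] + w[sub[i]] * tL[i])
    bt[i] <- s1a[i] + s1b[i]
    rt[i] <- pow(bt[i], pg) / (Z + pow(bt[i], qg))
    s1c[i] <- pow(nL[i], m[sub[i]]) / (S + nL[i] + w[sub[i]] * nR[i])
    s1d[i] <- pow(nR[i], m[sub[i]]) / (S + nR[i] + w[sub[i]] * nL[i])
    bn[i] <- s1c[i] + s1d[i]
    rn[i] <- pow(bn[i], pg) / (Z + pow(bn[i], qg))
    dpr[i] <- (rt[i] - rn[i]) / (k[sub[i]] / %.7f)
    pc[i] <- %g + %g * phi(dpr[i] / 1.41421356)
    r[i] ~ dbin(pc[i], n[i])
  }
}",
    priors$p[1], 1 / priors$p[2]^2, priors$q[1], 1 / priors$q[2]^2,
    priors$m[1], 1 / priors$m[2]^2, priors$omega[1], 1 / priors$omega[2]^2,
    priors$S[1], priors$S[2], priors$Z[1], priors$Z[2],
    priors$k[1], priors$k[2],
    priors$subject_sd[1], priors$subject_sd[2],
    priors$subject_sd[1], priors$subject_sd[2],
    priors$subject_sd[1], priors$subject_sd[2],
    tau_2ifc(), lapse / 2, 1 - lapse)
}

run_jags <- function(model_string, data, monitor, mcmc) {
  inits <- lapply(seq_len(mcmc$n_chains), function(i) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = sample.int(.Machine$integer.max, 1))
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = mcmc$n_chains,
                          n.adapt = mcmc$n_adapt, quiet = TRUE)
  if (mcmc$n_burnin > 0) {
    stats::update(jm, n.iter = mcmc$n_burnin, progress.bar = "none")
  }
  thin <- max(1L, as.integer(round(1 / mcmc$retain_fraction)))
  rjags::coda.samples(jm, monitor, n.iter = mcmc$n_iter, thin = thin,
                      progress.bar = "none")
}

marginal_mode <- function(x) {
  if (length(unique(x)) < 10) return(stats::median(x))
  d <- stats::density(x)
  d$x[which.max(d$y)]
}

summarize_posterior <- function(samp, mcmc) {
  mat <- do.call(rbind, lapply(samp, as.matrix))
  map <- apply(mat, 2, marginal_mode)
  ints <- apply(mat, 2, stats::quantile, probs = c(0.025, 0.975))
  psrf <- rep(NA_real_, ncol(mat)); names(psrf) <- colnames(mat)
  if (length(samp) > 1L) {
    gd <- try(coda::gelman.diag(samp, autoburnin = FALSE,
                                multivariate = FALSE), silent = TRUE)
    if (!inherits(gd, "try-error")) psrf <- gd$psrf[, 1]
  }
  neff <- coda::effectiveSize(samp)
  structure(list(samples = tibble::as_tibble(as.data.frame(mat)),
                 map_estimate = map, intervals = ints,
                 diagnostics = list(psrf = psrf, n_eff = neff),
                 converged = all(is.na(psrf) | psrf < 1.05),
                 retained_fraction = mcmc$retain_fraction,
                 mcmc = mcmc),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("Posterior summary (%d retained draws, %d chain%s%s)\n",
              nrow(x$samples), x$mcmc$n_chains,
              if (x$mcmc$n_chains > 1) "s" else "",
              if (x$converged) "" else "; NOT CONVERGED"))
  tab <- rbind(MAP = x$map_estimate, x$intervals)
  print(round(t(tab), 4))
  invisible(x)
}

#' Hierarchical Bayesian fit of the two-stage model to trial data
#'
#' Fits the seven-parameter model to trial-level 2IFC data with a
#' binomial likelihood: each cell's probability correct comes from the
#' model d-prime through the standard 2IFC link (fixed lapse rate).
#' Participant-level `m`, `omega` and `k` are partially pooled
#' (log-normal around group means with their own SDs); `p`, `q`, `S`
#' and `Z` are shared at group level. Priors follow [default_priors()]:
#' Gaussian on p, q, m, omega; uniform on S, Z, k. Sampling is MCMC via
#' JAGS; a `retain_fraction` of draws is kept by thinning. Group-level
#' parameters are reported as `pg`, `qg`, `mg` (m), `wg` (omega), `kg`,
#' `S`, `Z`.
#'
#' @param trials Trial table from one experiment/pathway (tibble or CSV
#'   path).
#' @param priors A [default_priors()] list.
#' @param mcmc An [mcmc_config()] list.
#' @param lapse Fixed lapse rate in the likelihood.
#'
#' @return A `posterior_summary`: retained `samples`, marginal
#'   `map_estimate`s, central 95% `intervals`, convergence
#'   `diagnostics` (split-chain PSRF when more than one chain, effective
#'   sample sizes). Unconverged chains are flagged, not errors.
#' @export
bayes_fit <- function(trials, priors = default_priors(),
                      mcmc = mcmc_config(), lapse = 0.01) {
  if (is.character(trials)) trials <- read_trial_table(trials)
  cells <- trials_to_cells(trials)
  data <- list(N = cells$n_cells, nsub = cells$n_sub, sub = cells$sub,
               tL = cells$tL, tR = cells$tR, nL = cells$nL,
               nR = cells$nR, r = cells$r, n = cells$n)
  samp <- run_jags(gain_jags_model(priors, lapse), data,
                   c("pg", "qg", "mg", "wg", "S", "Z", "kg"), mcmc)
  summarize_posterior(samp, mcmc)
}

crosspath_jags_model <- function(z_range, w_range, lapse) {
  sprintf("model {
  for (j in 1:3) { Zf[j] ~ dunif(%g, %g) }
  for (j in 1:6) { wf[j] ~ dunif(%g, %g) }
  W[1, 1] <- wd[1]
  W[1, 2] <- wf[1]
  W[1, 3] <- wf[2]
  W[2, 1] <- wf[3]
  W[2, 2] <- wd[2]
  W[2, 3] <- wf[4]
  W[3, 1] <- wf[5]
  W[3, 2] <- wf[6]
  W[3, 3] <- wd[3]
  for (i in 1:N) {
    supTa[i] <- inprod(W[tp[i], 1:3], CtR[i, 1:3])
    supTb[i] <- inprod(W[tp[i], 1:3], CtL[i, 1:3])
    s1a[i] <- pow(CtL[i, tp[i]], m[tp[i]]) /
              (S[tp[i]] + CtL[i, tp[i]] + supTa[i])
    s1b[i] <- pow(CtR[i, tp[i]], m[tp[i]]) /
              (S[tp[i]] + CtR[i, tp[i]] + supTb[i])
    bt[i] <- s1a[i] + s1b[i]
    rt[i] <- pow(bt[i], p[tp[i]]) / (Zf[tp[i]] + pow(bt[i], q[tp[i]]))
    supNa[i] <- inprod(W[tp[i], 1:3], CnR[i, 1:3])
    supNb[i] <- inprod(W[tp[i], 1:3], CnL[i, 1:3])
    s1c[i] <- pow(CnL[i, tp[i]], m[tp[i]]) /
              (S[tp[i]] + CnL[i, tp[i]] + supNa[i])
    s1d[i] <- pow(CnR[i, tp[i]], m[tp[i]]) /
              (S[tp[i]] + CnR[i, tp[i]] + supNb[i])
    bn[i] <- s1c[i] + s1d[i]
    rn[i] <- pow(bn[i], p[tp[i]]) / (Zf[tp[i]] + pow(bn[i], q[tp[i]]))
    dpr[i] <- (rt[i] - rn[i]) / (k[tp[i]] / %.7f)
    pc[i] <- %g + %g * phi(dpr[i] / 1.41421356)
    r[i] ~ dbin(pc[i], n[i])
  }
}", z_range[1], z_range[2], w_range[1], w_range[2],
    tau_2ifc(), lapse / 2, 1 - lapse)
}

# Aggregate an Experiment-2-style trial table into binomial cells with
# full per-pathway eye contrasts for both intervals.
exp2_trials_to_cells <- function(trials) {
  key <- interaction(trials$pathway_target, trials$pathway_mask,
                     trials$pedestal_norm, signif(trials$target_norm, 8),
                     drop = TRUE)
  idx <- split(seq_len(nrow(trials)), key)
  n <- length(idx)
  CtL <- CtR <- CnL <- CnR <- matrix(0, n, 3)
  tp <- integer(n); r <- nt <- numeric(n)
  for (i in seq_len(n)) {
    rows <- idx[[i]]
    tr <- trials[rows[1], ]
    cond <- masking_condition(tr$pathway_target, tr$pathway_mask,
                              tr$pedestal_norm)
    cc <- crosspath_contrasts(cond, tr$target_norm)
    CtL[i, ] <- cc$target$left; CtR[i, ] <- cc$target$right
    CnL[i, ] <- cc$null$left; CnR[i, ] <- cc$null$right
    tp[i] <- match(tr$pathway_target, pathways())
    r[i] <- sum(trials$correct[rows]); nt[i] <- length(rows)
  }
  list(N = n, tp = tp, CtL = CtL, CtR = CtR, CnL = CnL, CnR = CnR,
       r = r, n = nt)
}

#' Bayesian fit of the cross-pathway model to dichoptic masking data
#'
#' Estimates the nine free parameters of the cross-pathway extension — a
#' stage-2 `Z` per mechanism and the six cross-pathway interocular
#' suppression weights — from Experiment-2-style binomial trial data.
#' The within-pathway parameters (`p`, `q`, `m`, `S`, `k` and the
#' diagonal weights `omega`) are held fixed at the supplied model's
#' values; data are pooled over participants. Uniform priors on the free
#' parameters.
#'
#' @param trials Experiment-2-style trial table (tibble or CSV path).
#' @param fixed_model A [crosspath_model()] carrying the fixed
#'   within-pathway parameters (diagonal weights from its mechanisms).
#' @param z_range,w_range Uniform prior ranges for the per-mechanism Z
#'   and the six cross weights.
#' @inheritParams bayes_fit
#'
#' @return A `posterior_summary` over `Zf[1..3]` (AC, RG, BY) and
#'   `wf[1..6]` (cross weights in row order `W[1,2], W[1,3], W[2,1],
#'   W[2,3], W[3,1], W[3,2]` with pathways ordered AC, RG, BY).
#' @export
bayes_fit_crosspath <- function(trials,
                                fixed_model = default_crosspath_model(),
                                z_range = c(1e-4, 1), w_range = c(0, 3),
                                mcmc = mcmc_config(), lapse = 0.01) {
  if (is.character(trials)) trials <- read_trial_table(trials)
  cells <- exp2_trials_to_cells(trials)
  mech <- fixed_model$mechanisms
  getv <- function(f) vapply(pathways(), function(pw) mech[[pw]][[f]],
                             numeric(1))
  data <- c(cells, list(p = getv("p"), q = getv("q"), m = getv("m"),
                        S = getv("S"), k = getv("k"),
                        wd = unname(diag(fixed_model$weights))))
  samp <- run_jags(crosspath_jags_model(z_range, w_range, lapse), data,
                   c("Zf", "wf"), mcmc)
  summarize_posterior(samp, mcmc)
}

#' Extract the fitted 3x3 weight matrix from a cross-pathway posterior
#'
#' @param fit A `posterior_summary` from [bayes_fit_crosspath()].
#' @param fixed_model The model whose diagonal weights were held fixed.
#' @param estimate `"map"` or `"median"`.
#' @return A 3x3 weight matrix `W[target, mask]`.
#' @export
crosspath_weight_matrix <- function(fit, fixed_model,
                                    estimate = c("map", "median")) {
  estimate <- match.arg(estimate)
  v <- if (estimate == "map") fit$map_estimate
       else apply(as.matrix(fit$samples), 2, stats::median)
  W <- diag(diag(fixed_model$weights))
  off <- c("wf[1]", "wf[2]", "wf[3]", "wf[4]", "wf[5]", "wf[6]")
  pos <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  for (i in seq_len(6)) W[pos[i, 1], pos[i, 2]] <- v[[off[i]]]
  dimnames(W) <- list(pathways(), pathways())
  W
}
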