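bg_log <- function(...) {
  if (isTRUE(getOption("binocgain.verbose", TRUE))) {
    message("[", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "] ", ...)
  }
  invisible(NULL)
}

config_schema <- function() {
  list(
    experiment = c("exp1", "exp2", "exp3"),
    seed = "integer",
    out_prefix = "character",
    params_set = "character",
    lapse = "numeric",
    n_participants = "integer",
    jitter_sd = "numeric",
    design = NULL,   # validated against the experiment's design function
    fit = NULL       # validated in cmd_fit
  )
}

#' Read and validate a simulation/fit configuration file
#'
#' YAML with flat keys plus optional `design:` and `fit:` sections.
#' Unknown keys are errors (fail loudly). Recognized top-level keys:
#' `experiment` (exp1/exp2/exp3), `seed`, `out_prefix`, `params_set`
#' (a name from [example_params()]), `lapse`, `n_participants`,
#' `jitter_sd`, `design` (arguments to [exp1_design()] or
#' [exp2_design()]), `fit` (`method`: none/simplex/bayes, `free`,
#' `n_starts`).
#'
#' @param path Path to a YAML config file.
#' @return A named list with class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg))) {
    stop("malformed config: expected a keyed mapping", call. = FALSE)
  }
  unknown <- setdiff(names(cfg), names(config_schema()))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$experiment) ||
      !cfg$experiment %in% c("exp1", "exp2", "exp3")) {
    stop("config must name an experiment (exp1, exp2 or exp3)",
         call. = FALSE)
  }
  design_fun <- if (cfg$experiment == "exp2") exp2_design else exp1_design
  if (!is.null(cfg$design)) {
    bad <- setdiff(names(cfg$design), names(formals(design_fun)))
    if (length(bad)) {
      stop("unknown design key(s) for ", cfg$experiment, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(cfg$fit)) {
    bad <- setdiff(names(cfg$fit), c("method", "free", "n_starts"))
    if (length(bad)) {
      stop("unknown fit key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

provenance <- function(seed, config_path = NULL, extra = list()) {
  c(list(seed = seed,
         package = "binocgain",
         version = as.character(utils::packageVersion("binocgain")),
         config = if (!is.null(config_path)) basename(config_path),
         config_md5 = if (!is.null(config_path))
           unname(tools::md5sum(config_path)),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    extra)
}

#' Simulate an experiment from a config file
#'
#' Generates the trial table named by the config, writes it as CSV with
#' a JSON provenance sidecar (seed, config hash, package version), and
#' returns the table invisibly. Deterministic given (config, seed).
#'
#' @param config_path Path to a YAML config (see [read_run_config()]).
#' @param out_dir Output directory.
#' @param seed Integer seed; overrides the config's `seed` key.
#' @return The trial table, invisibly.
#' @export
cmd_simulate <- function(config_path, out_dir = ".", seed = NULL) {
  cfg <- read_run_config(config_path)
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  t0 <- Sys.time()
  bg_log("simulate: experiment=", cfg$experiment, " seed=", seed)
  set.seed(seed)
  npar <- cfg$n_participants %||% 3L
  jsd <- cfg$jitter_sd %||% 0.1
  if (cfg$experiment == "exp2") {
    design <- do.call(exp2_design, cfg$design %||% list())
    trials <- generate_experiment2(n_participants = npar,
                                   jitter_sd = jsd, design = design)
  } else {
    design <- do.call(exp1_design, cfg$design %||% list())
    if (cfg$experiment == "exp1") {
      pp <- NULL
      if (!is.null(cfg$params_set)) {
        pp <- list(AC = example_params(cfg$params_set))
      }
      trials <- generate_experiment1(pp, n_participants = npar,
                                     jitter_sd = jsd, design = design)
    } else {
      params <- example_params(cfg$params_set %||% "flicker_disc")
      trials <- generate_experiment3(params, n_participants = npar,
                                     jitter_sd = jsd, design = design)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- cfg$out_prefix %||% paste0("trials_", cfg$experiment)
  csv <- file.path(out_dir, paste0(prefix, ".csv"))
  write_trial_table(trials, csv)
  jsonlite::write_json(
    provenance(seed, config_path, list(n_trials = nrow(trials))),
    file.path(out_dir, paste0(prefix, "_provenance.json")),
    auto_unbox = TRUE, pretty = TRUE, null = "null")
  bg_log("simulate: wrote ", nrow(trials), " trials to ", csv, " (",
         round(as.numeric(Sys.time() - t0, units = "secs"), 1), " s)")
  invisible(trials)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_dipper_tables <- function(trials) {
  key <- interaction(trials$pathway_target, trials$arrangement,
                     trials$pedestal_norm, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(trials)), key), function(ix) {
    tr <- trials[ix, ]
    fit <- fit_psychometric(aggregate_trials(tr))
    tibble::tibble(pathway = tr$pathway_target[1],
                   arrangement = tr$arrangement[1],
                   pedestal_norm = tr$pedestal_norm[1],
                   threshold_norm = from_dB(fit$threshold_db),
                   threshold_db = fit$threshold_db,
                   sigma_db = fit$sigma_db, beta = fit$beta,
                   ci_lo_db = fit$ci_threshold[1],
                   ci_hi_db = fit$ci_threshold[2],
                   n_trials = fit$n_trials)
  })
  tab <- do.call(rbind, rows)
  tab[order(tab$pathway, tab$arrangement, tab$pedestal_norm), ]
}

dipper_summaries <- function(dippers) {
  out <- list()
  for (pw in unique(dippers$pathway)) {
    d <- dippers[dippers$pathway == pw, ]
    curve_of <- function(arr) {
      dd <- d[d$arrangement == arr, ]
      structure(tibble::tibble(pedestal_norm = dd$pedestal_norm,
                               threshold_norm = dd$threshold_norm),
                arrangement = arr,
                class = c("dipper_curve", "tbl_df", "tbl", "data.frame"))
    }
    mono <- curve_of("monocular"); bino <- curve_of("binocular")
    slopes <- sapply(intersect(arrangements(), d$arrangement),
                     function(a) {
                       cv <- curve_of(a)
                       if (sum(cv$pedestal_norm > 0) >= 4)
                         summarize_dipper(cv)$handle_slope else NA_real_
                     })
    at0 <- function(cv) {
      if (any(cv$pedestal_norm == 0))
        cv$threshold_norm[cv$pedestal_norm == 0][1] else NA_real_
    }
    out[[pw]] <- list(
      summation_ratio = at0(mono) / at0(bino),
      facilitation_factor = if (nrow(bino) && !is.na(at0(bino)))
        at0(bino) / min(bino$threshold_norm) else NA_real_,
      handle_slopes = as.list(slopes))
  }
  out
}

exp2_matrices <- function(trials) {
  conds <- unique(trials[, c("pathway_target", "pathway_mask")])
  fits <- list()
  for (i in seq_len(nrow(conds))) {
    ix <- trials$pathway_target == conds$pathway_target[i] &
      trials$pathway_mask == conds$pathway_mask[i]
    fits[[paste(conds$pathway_target[i], conds$pathway_mask[i],
                sep = ":")]] <- fit_psychometric(
                  aggregate_trials(trials[ix, ]))
  }
  elev <- slope <- matrix(NA_real_, 3, 3,
                          dimnames = list(target = pathways(),
                                          mask = pathways()))
  for (tpw in pathways()) {
    base <- fits[[paste(tpw, "none", sep = ":")]]
    if (is.null(base)) next
    for (mpw in pathways()) {
      f <- fits[[paste(tpw, mpw, sep = ":")]]
      if (is.null(f)) next
      elev[tpw, mpw] <- threshold_elevation(f, base)
      slope[tpw, mpw] <- f$beta
    }
  }
  baseline_beta <- sapply(pathways(), function(tpw) {
    f <- fits[[paste(tpw, "none", sep = ":")]]
    if (is.null(f)) NA_real_ else f$beta
  })
  list(threshold_elevation = elev, beta = slope,
       baseline_beta = baseline_beta, fits = fits)
}

#' Fit psychometric functions and models to a trial table
#'
#' Aggregates the trial table per condition, fits psychometric functions,
#' derives dipper tables and summary statistics (binocular summation
#' ratio, facilitation factor, handle slopes) for dipper-style data, and
#' the 3x3 threshold-elevation and psychometric-slope matrices for
#' cross-pathway masking data. Optionally refits the gain control model
#' (simplex and/or hierarchical Bayesian) as directed by the config's
#' `fit:` section.
#'
#' @param trials_path Path to a trial-table CSV (or a trial tibble).
#' @param config_path Optional YAML config; only its `fit:` section is
#'   used here (`method`: none/simplex/bayes, `free`, `n_starts`).
#' @param out_dir Optional output directory for the report files.
#' @param seed Seed used for any stochastic fitting stage.
#' @return An `analysis_report` list.
#' @export
cmd_fit <- function(trials_path, config_path = NULL, out_dir = NULL,
                    seed = 1L) {
  trials <- if (is.character(trials_path)) read_trial_table(trials_path)
            else trials_path
  if (nrow(trials) == 0L) stop("empty trial table", call. = FALSE)
  fit_cfg <- list(method = "none")
  if (!is.null(config_path)) {
    cfg <- read_run_config(config_path)
    fit_cfg <- utils::modifyList(fit_cfg, cfg$fit %||% list())
  }
  t0 <- Sys.time()
  report <- list(provenance = provenance(seed, config_path,
                                         list(n_trials = nrow(trials))))
  dip <- trials[trials$experiment %in% c("exp1", "exp3"), ]
  if (nrow(dip) > 0L) {
    bg_log("fit: psychometric fits for ", nrow(dip), " dipper trials")
    dippers <- fit_dipper_tables(dip)
    report$dipper_tables <- dippers
    report$dipper_summaries <- dipper_summaries(dippers)
    if (fit_cfg$method == "simplex") {
      bg_log("fit: simplex model fit")
      report$model_fits <- lapply(split(dippers, dippers$pathway),
        function(d) {
          fit <- simplex_fit(d, free = fit_cfg$free %||% c("omega", "m"),
                             params = example_params("meese2006"),
                             n_starts = fit_cfg$n_starts %||% 100L,
                             seed = seed)
          list(params = unclass(fit$params), rmse_db = fit$rmse_db,
               n_starts = fit$n_starts, best_start = fit$best_start)
        })
    } else if (fit_cfg$method == "bayes") {
      bg_log("fit: hierarchical Bayesian model fit")
      set.seed(seed)
      post <- bayes_fit(dip)
      report$model_fits <- list(posterior_map = as.list(post$map_estimate),
                                intervals = post$intervals,
                                converged = post$converged)
    }
  }
  xp <- trials[trials$experiment == "exp2", ]
  if (nrow(xp) > 0L) {
    bg_log("fit: cross-pathway masking matrices for ", nrow(xp),
           " trials")
    mats <- exp2_matrices(xp)
    report$exp2 <- list(threshold_elevation = mats$threshold_elevation,
                        beta = mats$beta,
                        baseline_beta = mats$baseline_beta)
  }
  if (is.null(report$dipper_tables) && is.null(report$exp2)) {
    stop("no recognizable experiment rows in the trial table",
         call. = FALSE)
  }
  class(report) <- c("analysis_report", "list")
  if (!is.null(out_dir)) write_report(report, out_dir)
  bg_log("fit: done in ",
         round(as.numeric(Sys.time() - t0, units = "secs"), 1), " s")
  report
}

#' Write / read an analysis report
#'
#' The report serializes to JSON (machine-readable, lossless for all
#' numeric tables) plus a human-readable text dump.
#'
#' @param report An `analysis_report` from [cmd_fit()] /
#'   [cmd_reproduce()].
#' @param out_dir Directory for `report.json` and `report.txt`.
#' @return `write_report()` the JSON path invisibly; `read_report()` the
#'   deserialized report list.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, null = "null")
  txt <- file.path(out_dir, "report.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines(utils::capture.output(utils::str(report, max.level = 3,
                                              give.attr = FALSE)), con)
  invisible(path)
}

#' @rdname write_report
#' @param path Path to a `report.json`.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Parameter-recovery reproduction of the fitted-parameter table
#'
#' For each stored parameter set (simplex or Bayesian rows of
#' [example_params()]), generates noiseless dipper thresholds from the
#' model over the standard pedestal grid and all four ocular
#' arrangements, refits with a subset of parameters free, and reports
#' recovered against generating values side by side. At `scale =
#' "desk"` the refit additionally runs a small hierarchical Bayesian fit
#' on stochastic trial data from the same generating parameters.
#'
#' @param table `"table1_simplex"` or `"table1_bayes"` — which stored
#'   parameter rows to reproduce.
#' @param scale `"demo"` (noiseless simplex refit only) or `"desk"`
#'   (adds a reduced-scale Bayesian fit).
#' @param free Parameters left free in the simplex refit.
#' @param n_starts Simplex starting vectors.
#' @param seed Integer seed.
#' @param sets Optional subset of parameter-set names to reproduce.
#' @param out_dir Optional output directory for the report.
#' @return An `analysis_report` with a `recovery` table.
#' @export
cmd_reproduce <- function(table = c("table1_simplex", "table1_bayes"),
                          scale = c("demo", "desk"),
                          free = "omega", n_starts = NULL, seed = 1L,
                          sets = NULL, out_dir = NULL) {
  table <- match.arg(table)
  scale <- match.arg(scale)
  all_sets <- if (table == "table1_simplex") {
    c("meese2006", "achromatic_grating", "lm_grating", "s_grating",
      "flicker_disc")
  } else {
    c("bayes_achromatic", "bayes_lm", "bayes_s", "bayes_flicker")
  }
  sets <- if (is.null(sets)) all_sets else intersect(all_sets, sets)
  if (!length(sets)) stop("no valid parameter sets selected",
                          call. = FALSE)
  n_starts <- n_starts %||% if (scale == "demo") 20L else 100L
  peds <- c(0, 0.5, 1, 2, 4, 8, 16, 32)
  rows <- list(); bayes <- list()
  for (s in sets) {
    gen <- example_params(s)
    bg_log("reproduce: ", s, " (", scale, " scale)")
    curves <- lapply(arrangements(), function(a)
      dipper_curve(peds, a, gen))
    fit <- simplex_fit(curves, free = free, params = gen,
                       n_starts = n_starts, seed = seed)
    rec <- unlist(fit$params[free])
    rows[[s]] <- tibble::tibble(
      set = s, parameter = free,
      generating = unname(unlist(gen[free])), recovered = unname(rec),
      rmse_db = fit$rmse_db)
    if (scale == "desk") {
      set.seed(seed + match(s, sets))
      tr <- generate_mocs_dipper(gen, n_participants = 3L,
                                 jitter_sd = 0.1)
      post <- bayes_fit(tr, mcmc = mcmc_config(n_chains = 1L,
                                               n_adapt = 300L,
                                               n_burnin = 300L,
                                               n_iter = 1500L))
      bayes[[s]] <- list(map = as.list(post$map_estimate),
                         converged = post$converged)
    }
  }
  report <- list(provenance = provenance(seed,
                                         extra = list(table = table,
                                                      scale = scale)),
                 recovery = do.call(rbind, rows))
  if (length(bayes)) report$bayes_recovery <- bayes
  class(report) <- c("analysis_report", "list")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}
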