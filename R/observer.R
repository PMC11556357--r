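#' Simulate Bernoulli 2IFC trial outcomes
#'
#' Draws correct/incorrect outcomes with the given probability correct,
#' using R's global RNG (seed with [set.seed()] for reproducibility).
#'
#' @param pc Probability correct, in `[0, 1]`; vectorized (one trial per
#'   element).
#'
#' @return Logical vector of trial outcomes.
#' @export
#' @examples
#' set.seed(1)
#' simulate_trial(rep(0.75, 5))
simulate_trial <- function(pc) {
  if (!is.numeric(pc) || any(!is.finite(pc)) || any(pc < 0 | pc > 1)) {
    stop("pc must be in [0, 1]", call. = FALSE)
  }
  stats::runif(length(pc)) < pc
}

#' 2IFC observer driven by the two-stage gain control model
#'
#' Returns a function mapping target level (dB re the normalized unit,
#' i.e. `20*log10(target_norm)`) to probability correct, for a fixed
#' pedestal and ocular arrangement: d-prime from the model, then the
#' standard 2IFC link with lapse rate `lapse`.
#'
#' @inheritParams solve_threshold
#' @param lapse Lapse rate of the simulated observer.
#'
#' @return A function `level_db -> probability correct`, monotone
#'   non-decreasing in level (up to the swan region under dichoptic
#'   masking).
#' @export
model_observer <- function(pedestal, arrangement, params, lapse = 0.01) {
  validate_gain_params(params)
  force(pedestal); force(arrangement); force(lapse)
  function(level_db) {
    dp <- response_difference(10^(level_db / 20), pedestal, arrangement,
                              params) / (params$k / params$tau)
    dprime_to_pc(dp, lapse)
  }
}

#' Configuration of a transformed up-down staircase
#'
#' The classic 3-down-1-up rule tracking the 79.4%-correct point
#' (\eqn{0.5^{1/3}}): the level drops one step after three consecutive
#' correct responses and rises one step after any incorrect response.
#' Steps are applied in the log (dB) domain.
#'
#' @param n_trials Trials per staircase.
#' @param step_db Step size in dB (default 3).
#' @param start_db Starting level in dB.
#' @param n_down,n_up Rule: `n_down` consecutive correct to go down, and
#'   the level rises after `n_up` incorrect (default 3-down-1-up).
#'
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(n_trials = 50L, step_db = 3, start_db = 10,
                             n_down = 3L, n_up = 1L) {
  if (n_trials < 1L || step_db <= 0 || n_down < 1L || n_up < 1L) {
    stop("invalid staircase configuration", call. = FALSE)
  }
  structure(list(n_trials = as.integer(n_trials), step_db = step_db,
                 start_db = start_db, n_down = as.integer(n_down),
                 n_up = as.integer(n_up)),
            class = "staircase_config")
}

#' Run one adaptive staircase against an observer
#'
#' @param cfg A [staircase_config()].
#' @param observer A function `level_db -> probability correct`
#'   (e.g. [model_observer()]); assumed monotone non-decreasing in level
#'   (not enforced).
#'
#' @return A list with `trials` (tibble: `trial`, `level_db`, `correct`,
#'   `reversal`) and `reversal_levels` (levels in dB at which the
#'   staircase changed direction).
#' @export
run_staircase <- function(cfg, observer) {
  stopifnot(inherits(cfg, "staircase_config"))
  n <- cfg$n_trials
  level <- numeric(n); correct <- logical(n); reversal <- logical(n)
  cur <- cfg$start_db
  streak <- 0L; wrong <- 0L; last_dir <- 0L
  for (i in seq_len(n)) {
    level[i] <- cur
    correct[i] <- simulate_trial(observer(cur))
    dir <- 0L
    if (correct[i]) {
      wrong <- 0L
      streak <- streak + 1L
      if (streak >= cfg$n_down) {
        cur <- cur - cfg$step_db; streak <- 0L; dir <- -1L
      }
    } else {
      streak <- 0L
      wrong <- wrong + 1L
      if (wrong >= cfg$n_up) {
        cur <- cur + cfg$step_db; wrong <- 0L; dir <- 1L
      }
    }
    if (dir != 0L && last_dir != 0L && dir != last_dir) {
      reversal[i] <- TRUE
    }
    if (dir != 0L) last_dir <- dir
  }
  list(trials = tibble::tibble(trial = seq_len(n), level_db = level,
                               correct = correct, reversal = reversal),
       reversal_levels = level[reversal])
}

#' Per-participant parameter jitter
#'
#' Draws participant-level parameters as log-normal jitter around the
#' group values (the structure the hierarchical Bayesian fit assumes).
#' Only `m`, `omega` and `k` vary across participants; `p`, `q`, `S`
#' and `Z` are shared.
#'
#' @param params Group-level [gain_params()].
#' @param sd Standard deviation of the jitter in log units (default 0.1).
#'
#' @return A `gain_params` object for one simulated participant.
#' @export
jitter_params <- function(params, sd = 0.1) {
  validate_gain_params(params)
  j <- exp(stats::rnorm(3, 0, sd))
  gain_params(p = params$p, q = params$q, m = params$m * j[1],
              S = params$S, Z = params$Z, omega = params$omega * j[2],
              k = params$k * j[3], tau = params$tau)
}

trial_table_columns <- function() {
  c("participant", "experiment", "pathway_target", "pathway_mask",
    "arrangement", "target_eye", "pedestal_norm", "target_norm",
    "correct", "block", "trial_index")
}

new_trial_table <- function(...) {
  tibble::tibble(...)[, trial_table_columns()]
}

#' Default design of the dipper experiment (Experiment-1 style)
#'
#' Pedestal grids are the printed stimulus values — achromatic
#' `{0, 0.5, 1, 2, 4, 8, 16, 32}`% Michelson contrast and chromatic
#' `{0, 1, 2, 4, 8, 16, 32, 64}`% of the maximum displayable cone
#' contrast (0.1 for L-M, 0.88 for S-(L+M)) — converted to normalized
#' units via each pathway's generating monocular detection threshold
#' (1% Michelson for AC; 0.004 and 0.035 cone contrast for RG and BY,
#' one sixteenth of the classic 16x-threshold mask contrasts).
#'
#' @param trials_per_staircase Trials per staircase per block (the block
#'   length is 8 staircases x this).
#' @param n_reps Repetitions of each pedestal per participant.
#' @param start_offset_db Staircase start level relative to the
#'   generating threshold, in dB.
#' @param step_db Staircase step in dB.
#' @param lapse Observer lapse rate.
#'
#' @return A list describing the design, including per-pathway
#'   `pedestals_norm` grids.
#' @export
exp1_design <- function(trials_per_staircase = 50L, n_reps = 3L,
                        start_offset_db = 10, step_db = 3, lapse = 0.01) {
  mono_thresh <- c(AC = 1, RG = 0.004, BY = 0.035)  # stimulus units
  grids <- list(
    AC = c(0, 0.5, 1, 2, 4, 8, 16, 32),             # % Michelson
    RG = c(0, 1, 2, 4, 8, 16, 32, 64) / 100 * 0.1,  # cone contrast
    BY = c(0, 1, 2, 4, 8, 16, 32, 64) / 100 * 0.88  # cone contrast
  )
  peds_norm <- Map(function(g, t0) g / t0, grids, as.list(mono_thresh))
  list(pedestals_norm = peds_norm, mono_thresh = mono_thresh,
       trials_per_staircase = as.integer(trials_per_staircase),
       n_reps = as.integer(n_reps), start_offset_db = start_offset_db,
       step_db = step_db, lapse = lapse)
}

# One block: 8 interleaved staircases (4 arrangements x 2 target eyes)
# at a single pedestal, emitted in round-robin interleaved trial order.
run_dipper_block <- function(params, pedestal, design, participant,
                             experiment, pathway, block) {
  combos <- expand.grid(arrangement = arrangements(),
                        target_eye = c("left", "right"),
                        stringsAsFactors = FALSE)
  pieces <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    arr <- combos$arrangement[i]
    gen_th <- solve_threshold(pedestal, arr, params)
    cfg <- staircase_config(n_trials = design$trials_per_staircase,
                            step_db = design$step_db,
                            start_db = 20 * log10(gen_th) +
                              design$start_offset_db)
    sc <- run_staircase(cfg, model_observer(pedestal, arr, params,
                                            design$lapse))
    pieces[[i]] <- tibble::tibble(
      staircase = i, within = sc$trials$trial,
      arrangement = arr, target_eye = combos$target_eye[i],
      target_norm = 10^(sc$trials$level_db / 20),
      correct = as.integer(sc$trials$correct))
  }
  tab <- do.call(rbind, pieces)
  tab <- tab[order(tab$within, tab$staircase), ]  # round-robin interleave
  new_trial_table(
    participant = participant, experiment = experiment,
    pathway_target = pathway, pathway_mask = "none",
    arrangement = tab$arrangement, target_eye = tab$target_eye,
    pedestal_norm = pedestal, target_norm = tab$target_norm,
    correct = tab$correct, block = block,
    trial_index = seq_len(nrow(tab)))
}

#' Simulate the dipper experiment (staircases, three pathways)
#'
#' For each participant, pathway, pedestal and repetition, runs a block
#' of 8 interleaved 3-down-1-up staircases (4 ocular arrangements x 2
#' target eyes) against the model observer.
#'
#' @param params_per_pathway Named list (`AC`, `RG`, `BY`) of group-level
#'   [gain_params()]; defaults to the simplex estimates for the three
#'   grating pathways.
#' @param n_participants Number of simulated participants.
#' @param jitter_sd Log-normal SD of per-participant parameter variation
#'   (see [jitter_params()]).
#' @param design An [exp1_design()] list.
#' @param seed Optional integer seed (sets the global RNG).
#'
#' @return A trial-table tibble (see [write_trial_table()] for columns).
#' @export
generate_experiment1 <- function(params_per_pathway = NULL,
                                 n_participants = 3L, jitter_sd = 0.1,
                                 design = exp1_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params_per_pathway)) {
    params_per_pathway <- list(AC = example_params("achromatic_grating"),
                               RG = example_params("lm_grating"),
                               BY = example_params("s_grating"))
  }
  out <- list()
  for (s in seq_len(n_participants)) {
    for (pw in names(params_per_pathway)) {
      ps <- jitter_params(params_per_pathway[[pw]], jitter_sd)
      peds <- design$pedestals_norm[[pw]]
      blk <- 0L
      for (rep_i in seq_len(design$n_reps)) {
        for (P in peds) {
          blk <- blk + 1L
          out[[length(out) + 1L]] <- run_dipper_block(
            ps, P, design, participant = paste0("S", s),
            experiment = "exp1", pathway = pw, block = blk)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Simulate the flickering-disc dipper experiment
#'
#' Identical machinery to [generate_experiment1()] — the model does not
#' distinguish flicker from gratings — run for a single achromatic
#' pathway with its own parameters and labelled `exp3`.
#'
#' @param params Group-level [gain_params()]; defaults to the
#'   flickering-disc estimates.
#' @inheritParams generate_experiment1
#' @export
generate_experiment3 <- function(params = example_params("flicker_disc"),
                                 n_participants = 3L, jitter_sd = 0.1,
                                 design = exp1_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- generate_experiment1(list(AC = params),
                              n_participants = n_participants,
                              jitter_sd = jitter_sd, design = design)
  tab$experiment <- "exp3"
  tab
}

#' Default design of the cross-pathway masking experiment
#'
#' 12 conditions (3 baseline detections + 9 factorial target x mask
#' pairings), each measured by the method of constant stimuli: 10 target
#' levels x 200 trials per block x 10 blocks per participant. Masks are
#' fixed at 16 times the mask pathway's monocular detection threshold.
#' Target levels are centred on the group model's predicted 75% point
#' for each condition, spaced 3 dB apart (chosen in advance, shared
#' across participants).
#'
#' @param mask_norm Mask contrast in mask-threshold units.
#' @param n_levels Number of target levels.
#' @param level_step_db Spacing of target levels in dB.
#' @param trials_per_block Trials per block (spread evenly over levels).
#' @param n_blocks Blocks (repetitions) per condition per participant.
#' @param lapse Observer lapse rate.
#' @export
exp2_design <- function(mask_norm = 16, n_levels = 10L, level_step_db = 3,
                        trials_per_block = 200L, n_blocks = 10L,
                        lapse = 0.01) {
  if (trials_per_block %% n_levels != 0L) {
    stop("trials_per_block must be a multiple of n_levels", call. = FALSE)
  }
  list(mask_norm = mask_norm, n_levels = as.integer(n_levels),
       level_step_db = level_step_db,
       trials_per_block = as.integer(trials_per_block),
       n_blocks = as.integer(n_blocks), lapse = lapse)
}

exp2_conditions <- function(design) {
  base <- data.frame(target_pathway = pathways(), mask_pathway = "none",
                     mask_contrast = 0, stringsAsFactors = FALSE)
  pairs <- expand.grid(target_pathway = pathways(),
                       mask_pathway = pathways(),
                       stringsAsFactors = FALSE)
  pairs$mask_contrast <- design$mask_norm
  rbind(base, pairs)
}

#' Simulate the cross-pathway dichoptic masking experiment
#'
#' Method of constant stimuli against the cross-pathway model observer.
#' With the default design and 3 participants this emits exactly
#' 12 conditions x 200 trials/block x 10 blocks x 3 participants =
#' 72,000 trials (each of the 10 levels carries 20 trials per block).
#'
#' @param model Group-level [crosspath_model()].
#' @param n_participants Number of simulated participants.
#' @param jitter_sd Log-normal SD of per-participant variation in each
#'   mechanism's `m`, `omega` and `k`.
#' @param design An [exp2_design()] list.
#' @param seed Optional integer seed.
#'
#' @return A trial-table tibble; `pedestal_norm` holds the mask contrast
#'   and `arrangement` is `"dichoptic_mocs"`.
#' @export
generate_experiment2 <- function(model = default_crosspath_model(),
                                 n_participants = 3L, jitter_sd = 0.1,
                                 design = exp2_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conds <- exp2_conditions(design)
  # target levels fixed in advance from the group model
  levels_by_cond <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    cond <- masking_condition(conds$target_pathway[i],
                              conds$mask_pathway[i],
                              conds$mask_contrast[i])
    t75 <- crosspath_threshold(cond, model)
    off <- (seq_len(design$n_levels) -
              (design$n_levels + 1) / 2) * design$level_step_db
    levels_by_cond[[i]] <- t75 * 10^(off / 20)
  }
  per_level <- design$trials_per_block %/% design$n_levels
  out <- list()
  for (s in seq_len(n_participants)) {
    mech <- lapply(model$mechanisms, jitter_params, sd = jitter_sd)
    pmod <- crosspath_model(mech, model$weights)
    for (i in seq_len(nrow(conds))) {
      cond <- masking_condition(conds$target_pathway[i],
                                conds$mask_pathway[i],
                                conds$mask_contrast[i])
      lev <- levels_by_cond[[i]]
      pc <- predict_psychometric(cond, lev, pmod, design$lapse)
      for (b in seq_len(design$n_blocks)) {
        lv_seq <- sample(rep(seq_along(lev), per_level))
        correct <- as.integer(simulate_trial(pc[lv_seq]))
        out[[length(out) + 1L]] <- new_trial_table(
          participant = paste0("S", s), experiment = "exp2",
          pathway_target = conds$target_pathway[i],
          pathway_mask = conds$mask_pathway[i],
          arrangement = "dichoptic_mocs",
          target_eye = if (b %% 2L == 1L) "left" else "right",
          pedestal_norm = conds$mask_contrast[i],
          target_norm = lev[lv_seq], correct = correct,
          block = b, trial_index = seq_along(lv_seq))
      }
    }
  }
  do.call(rbind, out)
}

#' Simulate a dipper experiment by the method of constant stimuli
#'
#' A compact generator used for parameter-recovery studies: fixed target
#' levels placed around each generating threshold, binomial trial counts
#' per level, per-participant parameter jitter. Closes the simulate-fit
#' loop without staircase path dependence.
#'
#' @inheritParams generate_experiment1
#' @param params Group-level [gain_params()].
#' @param pedestals Pedestal grid in normalized units.
#' @param arrs Ocular arrangements to include.
#' @param level_offsets_db Target levels relative to each generating
#'   threshold, in dB.
#' @param trials_per_level Trials at each level.
#' @param lapse Observer lapse rate.
#' @param pathway Pathway label stamped on the rows.
#' @export
generate_mocs_dipper <- function(params, pedestals = c(0, 1, 4, 16),
                                 arrs = arrangements(),
                                 level_offsets_db = seq(-6, 7.5,
                                                        length.out = 6),
                                 trials_per_level = 40L,
                                 n_participants = 3L, jitter_sd = 0.1,
                                 lapse = 0.01, pathway = "AC",
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (s in seq_len(n_participants)) {
    ps <- jitter_params(params, jitter_sd)
    blk <- 0L
    for (arr in arrs) for (P in pedestals) {
      blk <- blk + 1L
      t0 <- solve_threshold(P, arr, ps)
      lev <- t0 * 10^(level_offsets_db / 20)
      pc <- dprime_to_pc(dprime(lev, P, arr, ps), lapse)
      lv_seq <- rep(seq_along(lev), each = trials_per_level)
      correct <- as.integer(simulate_trial(pc[lv_seq]))
      out[[length(out) + 1L]] <- new_trial_table(
        participant = paste0("S", s), experiment = "exp1",
        pathway_target = pathway, pathway_mask = "none",
        arrangement = arr, target_eye = "left",
        pedestal_norm = P, target_norm = lev[lv_seq],
        correct = correct, block = blk, trial_index = seq_along(lv_seq))
    }
  }
  do.call(rbind, out)
}

#' Write / read a trial table as CSV
#'
#' Plain UTF-8 CSV with a header row and exactly the columns
#' `participant, experiment, pathway_target, pathway_mask, arrangement,
#' target_eye, pedestal_norm, target_norm, correct, block, trial_index`
#' (`correct` coded 0/1, `"."` decimal separator). The reader validates
#' the column set and round-trips losslessly.
#'
#' @param trials A trial-table tibble.
#' @param path File path.
#' @return `write_trial_table()` returns `path` invisibly;
#'   `read_trial_table()` returns the tibble.
#' @export
write_trial_table <- function(trials, path) {
  miss <- setdiff(trial_table_columns(), names(trials))
  if (length(miss)) {
    stop("trial table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(trials[, trial_table_columns()])
  df$correct <- as.integer(df$correct)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 fileEncoding = "UTF-8"),
                 error = function(e) {
                   stop("not a trial table (unparseable CSV: ",
                        conditionMessage(e), ")", call. = FALSE)
                 })
  miss <- setdiff(trial_table_columns(), names(df))
  if (length(miss)) {
    stop("not a trial table (missing columns: ",
         paste(miss, collapse = ", "), ")", call. = FALSE)
  }
  bad <- which(!df$correct %in% c(0L, 1L) | !is.finite(df$target_norm) |
                 df$target_norm <= 0 | df$pedestal_norm < 0)
  if (length(bad)) {
    stop("invalid trial rows at lines: ",
         paste(utils::head(bad + 1L, 10), collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df[, trial_table_columns()])
}
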