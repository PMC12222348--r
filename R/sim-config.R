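#' Simulation configuration for synthetic congruency-task data
#'
#' Builds the parameter set for the dual-process generative model behind
#' [simulate_dataset()]. Each trial's initiation time (IT) is the sum of a
#' participant baseline, a current-congruency effect, a previous-congruency
#' effect, and trial noise; movement time (MT) is a participant baseline plus
#' a current-congruency effect, an extra slowing on incongruent trials that
#' follow a congruent trial and repeat the previous response (cI-r trials),
#' an in-flight correction cost on partial-error trials, and trial noise.
#' Response time is IT + MT. All participant-level coefficients are drawn
#' from normal distributions with the means and SDs given here, so the
#' between-participant variance of each effect — and hence the true
#' reliability of the congruency-effect difference score — is known by
#' construction (see [true_reliability()]).
#'
#' Default effect magnitudes follow the keyboard flanker condition of the
#' release-and-press study this package models: congruency-effect mean/SD of
#' 30/36 ms for IT, 56/28 ms for MT. Baselines, trial-noise SDs, the
#' previous-congruency and cI-r magnitudes, and error/partial-error rates are
#' package conventions documented in the methods vignette.
#'
#' @param n_participants number of simulated participants.
#' @param n_blocks blocks per participant.
#' @param trials_per_block trials per block; must be even (half congruent,
#'   half incongruent, order randomized within block).
#' @param it_baseline_mean,it_baseline_sd between-participant distribution of
#'   the IT baseline (ms).
#' @param mt_baseline_mean,mt_baseline_sd between-participant distribution of
#'   the MT baseline (ms).
#' @param it_congruency_mean,it_congruency_sd between-participant distribution
#'   of the current-trial incongruency effect on IT (ms).
#' @param it_prev_congruency_mean,it_prev_congruency_sd between-participant
#'   distribution of the previous-trial incongruency effect on IT (ms).
#' @param mt_congruency_mean,mt_congruency_sd between-participant distribution
#'   of the current-trial incongruency effect on MT (ms).
#' @param mt_cIr_boost_mean,mt_cIr_boost_sd between-participant distribution
#'   of the extra MT on cI-r trials (incongruent, previous congruent,
#'   response repetition; ms).
#' @param it_noise_sd,mt_noise_sd within-participant trial noise SDs (ms).
#' @param partial_error_prob_incongruent,partial_error_prob_congruent
#'   probability that a reach starts toward the wrong target and is corrected
#'   in flight.
#' @param overt_error_prob_incongruent,overt_error_prob_congruent probability
#'   of an overt (uncorrected) error response.
#' @param commitment_fraction_mean,commitment_fraction_sd distribution of the
#'   fraction of the movement initially headed to the wrong target on
#'   partial-error trials; draws truncated to (0.01, 0.99).
#' @param mt_correction_cost MT cost (ms) of a full-commitment correction;
#'   partial-error trials pay `commitment_fraction * mt_correction_cost`.
#' @param start_point,target_left,target_right reach geometry in mm
#'   (2-D plane; numeric length-2 vectors).
#' @param sampling_rate trajectory sampling rate in Hz (trajectory mode).
#' @param onset_jitter_sd positional jitter SD (mm) before movement onset and
#'   laterally during the reach.
#' @param mode `"summary"` (trial table only) or `"trajectory"` (trial table
#'   plus raw trajectories for every trial).
#' @param age_group,condition_id labels stamped on every simulated trial.
#' @param seed integer seed making the simulated dataset reproducible.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_dataset()], [true_reliability()]
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 8, n_blocks = 2, trials_per_block = 16)
#' trials <- simulate_dataset(cfg)
#' head(trials)
sim_config <- function(n_participants = 51,
                       n_blocks = 4,
                       trials_per_block = 48,
                       it_baseline_mean = 350, it_baseline_sd = 50,
                       mt_baseline_mean = 300, mt_baseline_sd = 50,
                       it_congruency_mean = 30, it_congruency_sd = 36,
                       it_prev_congruency_mean = 12, it_prev_congruency_sd = 20,
                       mt_congruency_mean = 56, mt_congruency_sd = 28,
                       mt_cIr_boost_mean = 40, mt_cIr_boost_sd = 20,
                       it_noise_sd = 60, mt_noise_sd = 65,
                       partial_error_prob_incongruent = 0.15,
                       partial_error_prob_congruent = 0.03,
                       overt_error_prob_incongruent = 0.02,
                       overt_error_prob_congruent = 0.004,
                       commitment_fraction_mean = 0.3,
                       commitment_fraction_sd = 0.1,
                       mt_correction_cost = 100,
                       start_point = c(0, 0),
                       target_left = c(-100, 280),
                       target_right = c(100, 280),
                       sampling_rate = 100,
                       onset_jitter_sd = 0.5,
                       mode = c("summary", "trajectory"),
                       age_group = "adult",
                       condition_id = "keyboard",
                       seed = 1L) {
  mode <- match.arg(mode)
  cfg <- list(
    n_participants = n_participants, n_blocks = n_blocks,
    trials_per_block = trials_per_block,
    it_baseline_mean = it_baseline_mean, it_baseline_sd = it_baseline_sd,
    mt_baseline_mean = mt_baseline_mean, mt_baseline_sd = mt_baseline_sd,
    it_congruency_mean = it_congruency_mean,
    it_congruency_sd = it_congruency_sd,
    it_prev_congruency_mean = it_prev_congruency_mean,
    it_prev_congruency_sd = it_prev_congruency_sd,
    mt_congruency_mean = mt_congruency_mean,
    mt_congruency_sd = mt_congruency_sd,
    mt_cIr_boost_mean = mt_cIr_boost_mean,
    mt_cIr_boost_sd = mt_cIr_boost_sd,
    it_noise_sd = it_noise_sd, mt_noise_sd = mt_noise_sd,
    partial_error_prob_incongruent = partial_error_prob_incongruent,
    partial_error_prob_congruent = partial_error_prob_congruent,
    overt_error_prob_incongruent = overt_error_prob_incongruent,
    overt_error_prob_congruent = overt_error_prob_congruent,
    commitment_fraction_mean = commitment_fraction_mean,
    commitment_fraction_sd = commitment_fraction_sd,
    mt_correction_cost = mt_correction_cost,
    start_point = as.numeric(start_point),
    target_left = as.numeric(target_left),
    target_right = as.numeric(target_right),
    sampling_rate = sampling_rate,
    onset_jitter_sd = onset_jitter_sd,
    mode = mode,
    age_group = age_group,
    condition_id = condition_id,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks counts, probabilities, SDs, and geometry; called by [sim_config()]
#' and by [simulate_dataset()] on entry. Errors name the offending field.
#'
#' @param config a `sim_config` object (or a bare list with the same fields).
#' @return The config, invisibly, if valid.
#' @export
validate_sim_config <- function(config) {
  stopifnot(is.list(config))
  need_pos_count <- c("n_participants", "n_blocks", "trials_per_block")
  for (f in need_pos_count) {
    v <- config[[f]]
    if (is.null(v) || length(v) != 1 || !is.finite(v) || v < 1 || v != round(v)) {
      stop("invalid sim_config: `", f, "` must be a positive integer", call. = FALSE)
    }
  }
  if (config$trials_per_block %% 2 != 0 || config$trials_per_block < 2) {
    stop("invalid sim_config: `trials_per_block` must be even and >= 2",
         call. = FALSE)
  }
  sds <- grep("(_sd)$", names(config), value = TRUE)
  for (f in sds) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop("invalid sim_config: `", f, "` must be a finite SD >= 0", call. = FALSE)
    }
  }
  probs <- grep("^(partial|overt)_error_prob_", names(config), value = TRUE)
  for (f in probs) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("invalid sim_config: `", f, "` must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  if (config$commitment_fraction_mean <= 0 || config$commitment_fraction_mean >= 1) {
    stop("invalid sim_config: `commitment_fraction_mean` must lie in (0, 1)",
         call. = FALSE)
  }
  for (f in c("start_point", "target_left", "target_right")) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 2 || any(!is.finite(v))) {
      stop("invalid sim_config: `", f, "` must be a finite length-2 point (mm)",
           call. = FALSE)
    }
  }
  if (identical(config$start_point, config$target_left) ||
      identical(config$start_point, config$target_right)) {
    stop("invalid sim_config: `start_point` must differ from both targets",
         call. = FALSE)
  }
  if (!is.numeric(config$sampling_rate) || config$sampling_rate <= 0) {
    stop("invalid sim_config: `sampling_rate` must be positive (Hz)", call. = FALSE)
  }
  if (!config$mode %in% c("summary", "trajectory")) {
    stop("invalid sim_config: `mode` must be \"summary\" or \"trajectory\"",
         call. = FALSE)
  }
  invisible(config)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Field names match the arguments of [sim_config()]; missing fields take the
#' defaults. Format is chosen by file extension (`.yaml`/`.yml` vs `.json`).
#'
#' @param path path to a YAML or JSON file.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, " (use YAML or JSON)", call. = FALSE)
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d participants x %d blocks x %d trials (%s mode, seed %d)\n",
              x$n_participants, x$n_blocks, x$trials_per_block, x$mode, x$seed))
  cat(sprintf("  IT: base %g (sd %g), congruency %g (sd %g), prev %g (sd %g), noise %g\n",
              x$it_baseline_mean, x$it_baseline_sd, x$it_congruency_mean,
              x$it_congruency_sd, x$it_prev_congruency_mean,
              x$it_prev_congruency_sd, x$it_noise_sd))
  cat(sprintf("  MT: base %g (sd %g), congruency %g (sd %g), cI-r %g (sd %g), noise %g\n",
              x$mt_baseline_mean, x$mt_baseline_sd, x$mt_congruency_mean,
              x$mt_congruency_sd, x$mt_cIr_boost_mean, x$mt_cIr_boost_sd,
              x$mt_noise_sd))
  invisible(x)
}
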