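.required_trial_cols <- c("participant_id", "block", "trial_index",
                          "congruency", "target_side", "response_side",
                          "accuracy", "rt_ms")
.optional_trial_cols <- c("trial_uid", "it_ms", "mt_ms", "curv", "age_group",
                          "condition_id", "partial_error",
                          "commitment_fraction")

#' Read and validate a trial-level CSV
#'
#' Required columns: `participant_id`, `block`, `trial_index`, `congruency`,
#' `target_side`, `response_side`, `accuracy`, `rt_ms`. Optional: `it_ms`,
#' `mt_ms`, `curv`, `age_group`, `condition_id`, `trial_uid`. Congruency is
#' coerced to `"C"`/`"I"` (accepting `c`/`i`, `congruent`/`incongruent`,
#' `0`/`1`), accuracy to `"correct"`/`"error"` (accepting `1`/`0`). Schema
#' problems are reported with row numbers.
#'
#' @param path CSV file path.
#' @return A validated trial tibble; missing optional columns are listed in
#'   the `"missing_optional"` attribute.
#' @export
read_trial_table <- function(path) {
  stopifnot(file.exists(path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_trial_table(tab)
}

#' @rdname read_trial_table
#' @param trials a data frame to validate in place of a file.
#' @export
validate_trial_table <- function(trials) {
  trials <- tibble::as_tibble(trials)
  miss <- setdiff(.required_trial_cols, names(trials))
  if (length(miss) > 0) {
    stop("trial table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  cong <- tolower(as.character(trials$congruency))
  map <- c(c = "C", congruent = "C", "0" = "C", i = "I", incongruent = "I",
           "1" = "I")
  bad <- which(!cong %in% names(map))
  if (length(bad) > 0) {
    stop("unrecognized congruency value(s) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  trials$congruency <- unname(map[cong])

  acc <- tolower(as.character(trials$accuracy))
  amap <- c(correct = "correct", "1" = "correct", error = "error",
            "0" = "error")
  bad <- which(!acc %in% names(amap))
  if (length(bad) > 0) {
    stop("unrecognized accuracy value(s) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  trials$accuracy <- unname(amap[acc])

  for (colname in intersect(c("rt_ms", "it_ms", "mt_ms", "curv"),
                            names(trials))) {
    v <- suppressWarnings(as.numeric(trials[[colname]]))
    bad <- which(is.na(v) & !is.na(trials[[colname]]))
    if (length(bad) > 0) {
      stop("non-numeric ", colname, " at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    trials[[colname]] <- v
  }

  keycols <- intersect(c("participant_id", "condition_id", "block",
                         "trial_index"), names(trials))
  key <- do.call(paste, c(trials[keycols], sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate trial key at row(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  attr(trials, "missing_optional") <- setdiff(.optional_trial_cols,
                                              names(trials))
  trials
}

#' Write a trial table (RFC-4180 CSV with header)
#'
#' @param trials trial tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  readr::write_csv(trials, path, progress = FALSE)
  invisible(path)
}

#' Read a long-format trajectory CSV
#'
#' Columns `trial_uid`, `t_ms`, `x_mm`, `y_mm`, optionally `z_mm`.
#'
#' @param path CSV path.
#' @return A long trajectory tibble.
#' @export
read_trajectories <- function(path) {
  stopifnot(file.exists(path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("trial_uid", "t_ms", "x_mm", "y_mm")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("trajectory table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Run the full measurement-and-reliability pipeline
#'
#' Stage order: simulate (or ingest) -> trajectory measure extraction (when
#' trajectories are present) -> condition coding -> filtering -> optional
#' log transform -> per-participant effects -> split-half reliability ->
#' sequence ANOVAs. All stage outputs are written as CSV into `output_dir`
#' together with a JSON run manifest (config, seed, package version,
#' exclusion totals). With a simulation config and fixed seed the bundle is
#' byte-for-byte reproducible.
#'
#' @param config a [sim_config()] (simulation mode), or a list with element
#'   `trial_csv` (and optionally `trajectory_csv`) for file input.
#' @param output_dir directory for the report bundle (created if needed);
#'   `NULL` skips writing.
#' @param filter a [filter_config()].
#' @param measures measures to analyse (subset of rt/it/mt/curv).
#' @param score_types score types for the reliability stage.
#' @param n_permutations,reliability_seed split-half settings.
#' @param log_transform_measures if `TRUE`, effects/reliability/ANOVA are
#'   also computed on natural-log-transformed timing measures and written
#'   alongside (suffix `_log`).
#' @param min_trials minimum trials per cell for reliability.
#' @return A list: `trials`, `retained`, `exclusions`, `effects` (per
#'   measure), `descriptives`, `component_correlations`, `reliability`,
#'   `anova`, `manifest` (plus `_log` variants when requested).
#' @export
run_pipeline <- function(config,
                         output_dir = NULL,
                         filter = filter_config(),
                         measures = c("rt", "it", "mt"),
                         score_types = "difference",
                         n_permutations = 5000,
                         reliability_seed = 1L,
                         log_transform_measures = FALSE,
                         min_trials = 2) {
  # --- ingest or simulate ---------------------------------------------------
  trajectories <- NULL
  if (inherits(config, "sim_config")) {
    sim <- simulate_dataset(config)
    if (config$mode == "trajectory") {
      trials <- sim$trials
      trajectories <- sim$trajectories
    } else {
      trials <- sim
    }
    seed <- config$seed
  } else if (is.list(config) && !is.null(config$trial_csv)) {
    trials <- read_trial_table(config$trial_csv)
    if (!is.null(config$trajectory_csv)) {
      trajectories <- read_trajectories(config$trajectory_csv)
    }
    seed <- NA_integer_
  } else {
    stop("run_pipeline: config must be a sim_config or list(trial_csv = ...)",
         call. = FALSE)
  }

  # --- trajectory extraction ------------------------------------------------
  if (!is.null(trajectories)) {
    meas <- extract_measures_batch(trajectories)
    keep <- setdiff(names(trials), c("it_ms", "mt_ms", "rt_ms", "curv"))
    trials <- dplyr::left_join(trials[keep], meas, by = "trial_uid")
    trials <- trials[trials$measure_ok %in% TRUE, , drop = FALSE]
  }
  have_curv <- "curv" %in% names(trials) && any(!is.na(trials$curv))
  measures <- intersect(measures, c(.timing_measures, if (have_curv) "curv"))

  # --- coding and filtering -------------------------------------------------
  trials <- code_conditions(trials)
  filtered <- filter_trials(trials, filter)
  retained <- filtered$retained
  exclusions <- filtered$exclusions

  # error-rate path keeps errors/post-error trials (bounds only)
  err_cfg <- filter_config(rt_min = filter$rt_min,
                           rt_max_adult = filter$rt_max_adult,
                           rt_max_child = filter$rt_max_child,
                           exclude_errors = FALSE, exclude_post_error = FALSE,
                           apply_sd_rule = FALSE)
  err_retained <- filter_trials(trials, err_cfg)$retained

  analyse <- function(tab, measure_set) {
    eff <- lapply(measure_set, function(m) participant_condition_means(tab, m))
    names(eff) <- measure_set
    desc <- dplyr::bind_rows(lapply(measure_set, function(m) {
      d <- describe_effects(eff[[m]]$effect[!eff[[m]]$flagged])
      d$measure <- m
      dplyr::relocate(d, "measure")
    }))
    comp <- tibble::tibble(
      measure = measure_set,
      r_components = vapply(measure_set,
                            function(m) component_correlation(eff[[m]]),
                            numeric(1))
    )
    rel <- reliability_report(tab, measures = measure_set,
                              score_types = score_types,
                              n_permutations = n_permutations,
                              seed = reliability_seed,
                              min_trials = min_trials)
    anova <- dplyr::bind_rows(lapply(measure_set, function(m) {
      rm_anova_2x2x2(cell_means(tab, m))
    }))
    list(effects = eff, descriptives = desc, component_correlations = comp,
         reliability = rel, anova = anova)
  }

  out <- analyse(retained, measures)
  out$effects$error_rate <- participant_condition_means(err_retained,
                                                        "error_rate")
  res <- c(list(trials = trials, retained = retained,
                exclusions = exclusions), out)

  if (isTRUE(log_transform_measures)) {
    logt <- log_transform(retained,
                          paste0(intersect(measures, .timing_measures), "_ms"))
    res$log <- analyse(logt, intersect(measures, .timing_measures))
  }

  res$manifest <- list(
    package = "reachcong",
    version = as.character(utils::packageVersion("reachcong")),
    seed = seed,
    reliability_seed = reliability_seed,
    n_permutations = n_permutations,
    measures = measures,
    score_types = score_types,
    filter = unclass(filter),
    config = if (inherits(config, "sim_config")) unclass(config) else config,
    n_trials_input = nrow(trials),
    n_trials_retained = nrow(retained),
    exclusion_totals = as.list(tapply(exclusions$n_removed, exclusions$rule,
                                      sum))
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) readr::write_csv(x, file.path(output_dir, f),
                                         progress = FALSE)
    w(trials, "trials.csv")
    w(retained, "retained.csv")
    w(exclusions, "exclusions.csv")
    w(dplyr::bind_rows(res$effects), "participant_effects.csv")
    w(res$descriptives, "descriptives.csv")
    w(res$component_correlations, "component_correlations.csv")
    w(res$reliability, "reliability.csv")
    w(res$anova, "anova.csv")
    if (!is.null(trajectories)) w(trajectories, "trajectories.csv")
    jsonlite::write_json(res$manifest,
                         file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
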