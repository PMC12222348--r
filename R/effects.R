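measure_column <- function(trials, measure) {
  measure <- tolower(measure)
  col <- switch(measure,
                rt = "rt_ms", it = "it_ms", mt = "mt_ms", curv = "curv",
                error_rate = "accuracy",
                stop("unknown measure: ", measure, call. = FALSE))
  if (!col %in% names(trials)) {
    stop("measure `", measure, "` needs column `", col, "`", call. = FALSE)
  }
  col
}

#' Per-participant condition means and congruency-effect difference scores
#'
#' For timing and curvature measures, arithmetic means per participant and
#' congruency cell of the *filtered* trial table; for `"error_rate"`, the
#' proportion of overt errors per cell of a table that still contains error
#' trials (bounds-filtered but accuracy-unfiltered). The congruency effect
#' is always incongruent minus congruent.
#'
#' @param trials trial tibble (filtered as appropriate for the measure).
#' @param measure one of `"rt"`, `"it"`, `"mt"`, `"curv"`, `"error_rate"`.
#' @return A tibble with one row per participant: `participant_id`,
#'   `measure`, `mean_congruent`, `mean_incongruent`, `effect`,
#'   `n_congruent`, `n_incongruent`, `flagged` (empty cell).
#' @export
participant_condition_means <- function(trials, measure) {
  col <- measure_column(trials, measure)
  measure <- tolower(measure)
  val <- if (measure == "error_rate") {
    as.numeric(trials[[col]] == "error")
  } else {
    trials[[col]]
  }
  df <- tibble::tibble(participant_id = trials$participant_id,
                       congruency = trials$congruency, value = val)
  df <- df[!is.na(df$value), , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$participant_id),
    mean_congruent = mean(.data$value[.data$congruency == "C"]),
    mean_incongruent = mean(.data$value[.data$congruency == "I"]),
    n_congruent = sum(.data$congruency == "C"),
    n_incongruent = sum(.data$congruency == "I"),
    .groups = "drop"
  )
  out$measure <- measure
  out$effect <- out$mean_incongruent - out$mean_congruent
  out$flagged <- out$n_congruent < 1 | out$n_incongruent < 1
  dplyr::relocate(out, "participant_id", "measure", "mean_congruent",
                  "mean_incongruent", "effect")
}

#' Descriptive statistics of a congruency-effect distribution
#'
#' Sample mean, sample SD (n-1), min, max, adjusted Fisher-Pearson skewness,
#' and sample excess kurtosis — the layout used for congruency-effect
#' summary tables. Skew and kurtosis use the small-sample-adjusted
#' estimators (e1071 type 2, as in SPSS/Excel); excess kurtosis can be
#' negative. A constant vector yields SD 0 with skew/kurtosis `NA` and a
#' degeneracy flag.
#'
#' @param effects numeric vector of per-participant effects (n >= 4).
#' @return A one-row tibble `n`, `mean`, `sd`, `min`, `max`, `skew`,
#'   `kurtosis`, `degenerate`.
#' @export
describe_effects <- function(effects) {
  effects <- effects[!is.na(effects)]
  n <- length(effects)
  if (n < 4) {
    stop("describe_effects needs at least 4 values (kurtosis undefined)",
         call. = FALSE)
  }
  s <- sd(effects)
  degenerate <- s == 0
  tibble::tibble(
    n = n,
    mean = mean(effects),
    sd = s,
    min = min(effects),
    max = max(effects),
    skew = if (degenerate) NA_real_ else e1071::skewness(effects, type = 2),
    kurtosis = if (degenerate) NA_real_ else e1071::kurtosis(effects, type = 2),
    degenerate = degenerate
  )
}

#' Correlation between congruent and incongruent component scores
#'
#' Pearson correlation, across participants, of the congruent-cell mean with
#' the incongruent-cell mean — the component correlation that bounds the
#' reliability a difference score can achieve.
#'
#' @param participant_effects output of [participant_condition_means()];
#'   flagged participants are dropped.
#' @return Scalar correlation; `NA` with a warning if either component has
#'   zero variance or fewer than 3 participants remain.
#' @export
component_correlation <- function(participant_effects) {
  pe <- participant_effects[!participant_effects$flagged, , drop = FALSE]
  if (nrow(pe) < 3) {
    warning("component_correlation: fewer than 3 complete participants")
    return(NA_real_)
  }
  if (sd(pe$mean_congruent) == 0 || sd(pe$mean_incongruent) == 0) {
    warning("component_correlation: zero variance in a component")
    return(NA_real_)
  }
  cor(pe$mean_congruent, pe$mean_incongruent)
}
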