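.anova_effects <- c("congruency_n", "congruency_prev", "repetition",
                    "n_x_prev", "n_x_rep", "prev_x_rep", "n_x_prev_x_rep")

#' Per-participant 2 x 2 x 2 cell means
#'
#' Unweighted arithmetic means per participant for the eight cells of the
#' sequence design: trial-n congruency (C/I) x trial n-1 congruency (c/i) x
#' response repetition type (alternation/repetition). First-of-block trials
#' (no n-1 codes) are excluded. Participants with any empty cell are flagged
#' and excluded listwise by [rm_anova_2x2x2()].
#'
#' @param trials condition-coded (and typically filtered) trial tibble.
#' @param measure `"rt"`, `"it"`, `"mt"`, or `"curv"`.
#' @return A tibble: `participant_id`, `measure`, `congruency_n`,
#'   `prev_congruency`, `response_repetition`, `cell_mean`, `n_trials`,
#'   `complete` (participant-level flag).
#' @export
cell_means <- function(trials, measure) {
  col <- measure_column(trials, measure)
  t2 <- trials[trials$prev_congruency %in% c("c", "i") &
                 trials$response_repetition %in% c("alternation", "repetition") &
                 !is.na(trials[[col]]), , drop = FALSE]
  grid <- expand.grid(
    participant_id = unique(t2$participant_id),
    congruency_n = c("C", "I"),
    prev_congruency = c("c", "i"),
    response_repetition = c("alternation", "repetition"),
    stringsAsFactors = FALSE
  )
  agg <- dplyr::summarise(
    dplyr::group_by(t2, .data$participant_id, congruency_n = .data$congruency,
                    .data$prev_congruency, .data$response_repetition),
    cell_mean = mean(.data[[col]]),
    n_trials = dplyr::n(),
    .groups = "drop"
  )
  out <- dplyr::left_join(tibble::as_tibble(grid), agg,
                          by = c("participant_id", "congruency_n",
                                 "prev_congruency", "response_repetition"))
  out$n_trials[is.na(out$n_trials)] <- 0L
  comp <- dplyr::summarise(dplyr::group_by(out, .data$participant_id),
                           complete = all(.data$n_trials > 0),
                           .groups = "drop")
  out <- dplyr::left_join(out, comp, by = "participant_id")
  out$measure <- tolower(measure)
  dplyr::arrange(out, .data$participant_id, .data$congruency_n,
                 .data$prev_congruency, .data$response_repetition)
}

#' Within-subject 2 x 2 x 2 ANOVA via contrast scores
#'
#' For each of the seven effects (three mains, three two-ways, one
#' three-way), a per-participant contrast score is formed from the eight
#' cell means with +/-1 weights (products of the factors' sign codes), and
#' `F(1, N-1) = N * mean(contrast)^2 / var(contrast)` — identical to the
#' squared paired t statistic and to the standard repeated-measures ANOVA F
#' for 2-level within factors. Participants with any empty cell are
#' excluded listwise.
#'
#' @param cellmeans output of [cell_means()].
#' @return A tibble: `measure`, `effect`, `F`, `df1`, `df2`, `p`,
#'   `contrast_mean`, `n_participants`. Zero contrast variance gives
#'   `F = NA` (flagged via `p = NA`).
#' @export
rm_anova_2x2x2 <- function(cellmeans) {
  cm <- cellmeans[cellmeans$complete, , drop = FALSE]
  pids <- unique(cm$participant_id)
  n <- length(pids)
  if (n < 3) stop("rm_anova_2x2x2 needs >= 3 complete participants", call. = FALSE)

  # rows of cell_means are sorted; build N x 8 matrix in that cell order
  cm <- dplyr::arrange(cm, .data$participant_id, .data$congruency_n,
                       .data$prev_congruency, .data$response_repetition)
  m <- matrix(cm$cell_mean, nrow = n, ncol = 8, byrow = TRUE)

  key <- unique(cm[, c("congruency_n", "prev_congruency",
                       "response_repetition")])
  a <- ifelse(key$congruency_n == "I", 1, -1)
  b <- ifelse(key$prev_congruency == "i", 1, -1)
  c3 <- ifelse(key$response_repetition == "repetition", 1, -1)
  weights <- list(
    congruency_n = a, congruency_prev = b, repetition = c3,
    n_x_prev = a * b, n_x_rep = a * c3, prev_x_rep = b * c3,
    n_x_prev_x_rep = a * b * c3
  )

  rows <- lapply(.anova_effects, function(eff) {
    cs <- as.numeric(m %*% weights[[eff]])
    v <- var(cs)
    if (v == 0) {
      return(tibble::tibble(measure = cm$measure[1], effect = eff,
                            F = NA_real_, df1 = 1L, df2 = n - 1L,
                            p = NA_real_, contrast_mean = mean(cs),
                            n_participants = n))
    }
    f <- n * mean(cs)^2 / v
    tibble::tibble(measure = cm$measure[1], effect = eff, F = f, df1 = 1L,
                   df2 = n - 1L, p = pf(f, 1, n - 1, lower.tail = FALSE),
                   contrast_mean = mean(cs), n_participants = n)
  })
  dplyr::bind_rows(rows)
}
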