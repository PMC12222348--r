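#' Spearman-Brown correction
#'
#' Projects a half-length split-half correlation to full test length:
#' `2 * r / (1 + r)`. Strictly increasing on (-1, 1], fixing 0 and 1.
#' Values at or below -1 (degenerate splits) return `NA` so callers can
#' count them as invalid.
#'
#' @param r half-length Pearson correlation(s).
#' @return Corrected reliability, same length as `r`.
#' @export
#' @examples
#' spearman_brown(0.5)   # 0.667
#' spearman_brown(-1/3)  # -1
spearman_brown <- function(r) {
  out <- 2 * r / (1 + r)
  out[!is.na(r) & r <= -1] <- NA_real_
  out
}

#' Qualitative reliability label
#'
#' Bins a reliability estimate, rounded to two decimals, into the
#' conventional cutoffs: below 0.70 poor, 0.70-0.79 acceptable, 0.80-0.89
#' good, 0.90 and above excellent.
#'
#' @param r finite reliability estimate(s).
#' @return Character vector of labels.
#' @export
#' @examples
#' classify_reliability(c(0.69, 0.70, 0.894, 0.90))
classify_reliability <- function(r) {
  r2 <- round(r, 2)
  out <- rep(NA_character_, length(r))
  out[r2 < 0.70] <- "poor"
  out[r2 >= 0.70 & r2 < 0.80] <- "acceptable"
  out[r2 >= 0.80 & r2 < 0.90] <- "good"
  out[r2 >= 0.90] <- "excellent"
  out
}

#' Analytic reliability of a difference score
#'
#' The classical identity linking the reliability of a difference score to
#' the reliabilities of its components and their intercorrelation:
#' \deqn{r_{dd} = \frac{r_{xx} s_x^2 + r_{yy} s_y^2 - 2 r_{xy} s_x s_y}
#'                     {s_x^2 + s_y^2 - 2 r_{xy} s_x s_y}}
#' Highly reliable components that correlate strongly still yield an
#' unreliable difference — the structural reason congruency effects can
#' show poor reliability while their component scores look excellent.
#'
#' @param r_xx,r_yy component reliabilities.
#' @param r_xy correlation between the component scores.
#' @param s_x,s_y component standard deviations (> 0).
#' @return Difference-score reliability.
#' @export
#' @examples
#' difference_score_reliability_analytic(0.9, 0.9, 0.8, 10, 10) # 0.5
difference_score_reliability_analytic <- function(r_xx, r_yy, r_xy, s_x, s_y) {
  stopifnot(s_x > 0, s_y > 0)
  denom <- s_x^2 + s_y^2 - 2 * r_xy * s_x * s_y
  if (denom <= 0) {
    stop("difference-score reliability undefined: components essentially identical",
         call. = FALSE)
  }
  (r_xx * s_x^2 + r_yy * s_y^2 - 2 * r_xy * s_x * s_y) / denom
}

# --- permutation split-half engine -----------------------------------------

# Precomputes the per-cell layout so each permutation costs one runif, one
# radix order, and one rowsum over the trial vector.
split_engine_setup <- function(trials, measure, score_type, min_trials = 2) {
  col <- measure_column(trials, measure)
  val <- if (tolower(measure) == "error_rate") {
    as.numeric(trials[[col]] == "error")
  } else {
    trials[[col]]
  }
  keep <- !is.na(val) & trials$congruency %in% c("C", "I")
  if (score_type == "congruent_component") keep <- keep & trials$congruency == "C"
  if (score_type == "incongruent_component") keep <- keep & trials$congruency == "I"
  pid <- trials$participant_id[keep]
  cong <- trials$congruency[keep]
  val <- val[keep]

  # eligibility: >= min_trials in every stratum the score type needs
  tab <- table(pid, cong)
  ok <- apply(tab >= min_trials, 1, all)
  eligible <- rownames(tab)[ok]
  n_dropped <- sum(!ok)
  if (length(eligible) < 3) {
    stop("fewer than 3 participants with >= ", min_trials,
         " trials per required cell", call. = FALSE)
  }
  keep2 <- pid %in% eligible
  pid <- factor(pid[keep2])
  cong <- cong[keep2]
  val <- val[keep2]

  two_cells <- score_type == "difference"
  cell <- if (two_cells) {
    (as.integer(pid) - 1L) * 2L + ifelse(cong == "I", 2L, 1L)
  } else {
    as.integer(pid)
  }
  o0 <- order(cell)
  cell <- cell[o0]
  val <- val[o0]
  ng <- tabulate(cell)
  half <- ng %/% 2L
  pos <- sequence(ng)
  ishalf1 <- pos <= half[cell]
  id <- 2L * cell - as.integer(ishalf1) # 2c-1 = half1, 2c = half2
  cnt <- tabulate(id)

  list(val = val, cell = cell, id = id, cnt = cnt,
       n_cells = max(cell), n_participants = nlevels(pid),
       participants = levels(pid), two_cells = two_cells,
       n_dropped = n_dropped)
}

# One batch of split-half correlations; returns a numeric vector of Pearson
# r values (NA where a half had zero variance across participants).
split_engine_run <- function(setup, n_permutations) {
  n <- length(setup$val)
  r_out <- numeric(n_permutations)
  for (p in seq_len(n_permutations)) {
    o <- order(setup$cell, runif(n), method = "radix")
    sums <- rowsum(setup$val[o], setup$id, reorder = TRUE)
    means <- sums[, 1] / setup$cnt
    m1 <- means[seq(1, length(means), by = 2)] # half1 per cell
    m2 <- means[seq(2, length(means), by = 2)] # half2 per cell
    if (setup$two_cells) {
      idx_c <- seq(1, setup$n_cells, by = 2)
      idx_i <- idx_c + 1
      s1 <- m1[idx_i] - m1[idx_c]
      s2 <- m2[idx_i] - m2[idx_c]
    } else {
      s1 <- m1
      s2 <- m2
    }
    r_out[p] <- if (sd(s1) == 0 || sd(s2) == 0) {
      NA_real_
    } else {
      cor(s1, s2)
    }
  }
  r_out
}

#' One random split-half reliability
#'
#' Performs a single random split: within each participant x congruency cell
#' the trials are partitioned into halves of size floor(n/2) and ceil(n/2)
#' (membership random), half-wise scores are computed (difference score, or
#' a single condition's mean for component score types), the half-1 and
#' half-2 scores are correlated across participants (Pearson), and the
#' Spearman-Brown correction is applied. Uses the current RNG state.
#'
#' @param trials retained trial tibble (see [filter_trials()]).
#' @param measure `"rt"`, `"it"`, `"mt"`, `"curv"`, or `"error_rate"`.
#' @param score_type `"difference"`, `"congruent_component"`, or
#'   `"incongruent_component"`.
#' @param min_trials minimum trials per required cell per participant.
#' @return Spearman-Brown-corrected correlation (scalar; `NA` for an invalid
#'   split).
#' @export
split_half_once <- function(trials, measure, score_type = "difference",
                            min_trials = 2) {
  score_type <- match.arg(score_type, c("difference", "congruent_component",
                                        "incongruent_component"))
  setup <- split_engine_setup(trials, measure, score_type, min_trials)
  spearman_brown(split_engine_run(setup, 1L))
}

#' Permutation-based split-half reliability
#'
#' Repeats [split_half_once()] over many random splits and aggregates: the
#' estimate is the arithmetic mean of the valid Spearman-Brown-corrected
#' correlations, with a 95% interval given by the 2.5th and 97.5th
#' percentiles of the permutation distribution. Splits where a half has zero
#' variance across participants (or the half correlation is -1) are counted
#' as invalid and excluded; more than 10% invalid splits sets a warning
#' flag. Deterministic given `seed`.
#'
#' @inheritParams split_half_once
#' @param n_permutations number of random splits (default 5000).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return A one-row tibble: `measure`, `score_type`, `n_permutations`,
#'   `mean_r_sb`, `ci_low`, `ci_high`, `n_participants_used`,
#'   `n_dropped_participants`, `n_invalid_splits`, `label`,
#'   `high_invalid_rate`. The full permutation distribution is attached as
#'   attribute `"r_sb"`.
#' @export
permutation_reliability <- function(trials, measure,
                                    score_type = "difference",
                                    n_permutations = 5000,
                                    seed = NULL, min_trials = 2) {
  score_type <- match.arg(score_type, c("difference", "congruent_component",
                                        "incongruent_component"))
  if (!is.null(seed)) set.seed(seed)
  setup <- split_engine_setup(trials, measure, score_type, min_trials)
  r <- split_engine_run(setup, n_permutations)
  r_sb <- spearman_brown(r)
  valid <- r_sb[!is.na(r_sb)]
  n_invalid <- n_permutations - length(valid)
  if (length(valid) == 0) {
    stop("all splits invalid for measure ", measure, call. = FALSE)
  }
  est <- mean(valid)
  ci <- unname(quantile(valid, c(0.025, 0.975)))
  out <- tibble::tibble(
    measure = tolower(measure),
    score_type = score_type,
    n_permutations = as.integer(n_permutations),
    mean_r_sb = est,
    ci_low = ci[1],
    ci_high = ci[2],
    n_participants_used = setup$n_participants,
    n_dropped_participants = setup$n_dropped,
    n_invalid_splits = as.integer(n_invalid),
    label = classify_reliability(est),
    high_invalid_rate = n_invalid > 0.1 * n_permutations
  )
  attr(out, "r_sb") <- r_sb
  out
}

#' Reliability report across measures and score types
#'
#' Convenience wrapper running [permutation_reliability()] for every
#' combination of the requested measures and score types, mirroring the
#' layout of a reliability summary table (estimate, 95% CI, label).
#'
#' @inheritParams permutation_reliability
#' @param measures character vector of measures.
#' @param score_types character vector of score types.
#' @return Row-bound tibble of estimates.
#' @export
reliability_report <- function(trials, measures = c("rt", "it", "mt"),
                               score_types = c("difference",
                                               "congruent_component",
                                               "incongruent_component"),
                               n_permutations = 5000, seed = NULL,
                               min_trials = 2) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (m in measures) {
    for (st in score_types) {
      rows[[paste(m, st)]] <- permutation_reliability(
        trials, m, st, n_permutations = n_permutations, seed = NULL,
        min_trials = min_trials
      )
    }
  }
  dplyr::bind_rows(rows)
}
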