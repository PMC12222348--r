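#' Code trial-sequence conditions
#'
#' Derives, strictly within participant x condition x block and from the
#' immediately preceding trial: previous-trial congruency (`"c"`/`"i"`,
#' `"none"` on the first trial of a block), response repetition type
#' (`"repetition"`/`"alternation"`/`"none"`), a post-error flag (previous
#' trial was an overt error), and a first-of-block flag.
#'
#' @param trials trial tibble with `participant_id`, `block`, `trial_index`,
#'   `congruency` (`"C"`/`"I"`), `response_side`, `accuracy`; `condition_id`
#'   optional.
#' @return The input with columns `prev_congruency`,
#'   `response_repetition`, `post_error`, `first_of_block` added (replaced if
#'   present), rows ordered by participant, condition, block, trial.
#' @export
code_conditions <- function(trials) {
  need <- c("participant_id", "block", "trial_index", "congruency",
            "response_side", "accuracy")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) {
    stop("code_conditions: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  grp <- intersect(c("participant_id", "condition_id", "block"), names(trials))
  trials <- dplyr::arrange(trials, dplyr::across(dplyr::all_of(c(grp, "trial_index"))))
  key <- do.call(paste, c(trials[c(grp, "trial_index")], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate (participant, block, trial_index) rows: ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "),
         call. = FALSE)
  }
  trials <- dplyr::group_by(trials, dplyr::across(dplyr::all_of(grp)))
  trials <- dplyr::mutate(
    trials,
    first_of_block = dplyr::row_number() == 1L,
    prev_congruency = dplyr::if_else(
      .data$first_of_block, "none",
      tolower(dplyr::lag(.data$congruency))
    ),
    response_repetition = dplyr::case_when(
      .data$first_of_block ~ "none",
      dplyr::lag(.data$response_side) == .data$response_side ~ "repetition",
      TRUE ~ "alternation"
    ),
    post_error = !.data$first_of_block &
      dplyr::lag(.data$accuracy) == "error"
  )
  dplyr::ungroup(trials)
}

#' Trial-filter configuration
#'
#' The standard exclusion ladder: (1) first trial of each block, (2) overt
#' errors, (3) trials following an overt error, (4) absolute RT bounds
#' (under 200 ms, or over 2.5 s for adults / 4 s for children), (5) trials
#' with RT more than 3 SDs from the participant's own condition mean,
#' computed on the survivors of steps 1-4. Each stage can be toggled; the
#' error-rate analysis path, for instance, keeps errors and post-error
#' trials (`exclude_errors = FALSE`, `exclude_post_error = FALSE`,
#' `apply_sd_rule = FALSE`).
#'
#' @param rt_min lower RT bound in ms.
#' @param rt_max_adult,rt_max_child upper RT bounds in ms by age group.
#' @param sd_cutoff SD multiplier for the outlier rule.
#' @param exclude_first_of_block,exclude_errors,exclude_post_error,apply_sd_rule
#'   stage toggles.
#' @return A `filter_config` list.
#' @export
filter_config <- function(rt_min = 200, rt_max_adult = 2500,
                          rt_max_child = 4000, sd_cutoff = 3,
                          exclude_first_of_block = TRUE,
                          exclude_errors = TRUE,
                          exclude_post_error = TRUE,
                          apply_sd_rule = TRUE) {
  stopifnot(rt_min < rt_max_adult, rt_min < rt_max_child, sd_cutoff > 0)
  structure(list(rt_min = rt_min, rt_max_adult = rt_max_adult,
                 rt_max_child = rt_max_child, sd_cutoff = sd_cutoff,
                 exclude_first_of_block = exclude_first_of_block,
                 exclude_errors = exclude_errors,
                 exclude_post_error = exclude_post_error,
                 apply_sd_rule = apply_sd_rule),
            class = "filter_config")
}

.filter_rules <- c("first_of_block", "error", "post_error", "rt_bounds",
                   "sd_outlier")

#' Apply the exclusion ladder
#'
#' Applies the stages of [filter_config()] in fixed order; a trial is
#' attributed to the first rule that catches it, so per-rule counts are
#' additive. The SD stage recomputes each participant's mean and SD of RT
#' per congruency condition (within interface condition, if present) on the
#' survivors of the earlier stages. Filtering never alters measure values,
#' only membership. Participants left with fewer than 2 trials in either
#' congruency cell are retained but flagged (`low_trial`).
#'
#' @param trials condition-coded trial tibble (see [code_conditions()]); an
#'   `age_group` column of `"child"`/`"adult"` selects the RT bound
#'   (missing column means adult).
#' @param config a [filter_config()].
#' @return A list: `retained` (tibble, with `low_trial` flag column) and
#'   `exclusions` (tibble `participant_id`, `rule`, `n_removed`, one row per
#'   participant x rule, zeros included).
#' @export
filter_trials <- function(trials, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  need <- c("participant_id", "congruency", "accuracy", "rt_ms",
            "first_of_block", "post_error")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) {
    stop("filter_trials: missing column(s) (run code_conditions first?): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  age <- if ("age_group" %in% names(trials)) trials$age_group else "adult"
  rt_max <- ifelse(age == "child", config$rt_max_child, config$rt_max_adult)

  rule <- rep(NA_character_, nrow(trials))
  hit <- function(cond, name) {
    cond <- cond & is.na(rule)
    rule[cond] <<- name
  }
  if (config$exclude_first_of_block) hit(trials$first_of_block, "first_of_block")
  if (config$exclude_errors) hit(trials$accuracy == "error", "error")
  if (config$exclude_post_error) hit(trials$post_error, "post_error")
  hit(trials$rt_ms < config$rt_min | trials$rt_ms > rt_max, "rt_bounds")

  if (config$apply_sd_rule) {
    surv <- is.na(rule)
    cellcols <- intersect(c("participant_id", "condition_id", "congruency"),
                          names(trials))
    cell <- do.call(paste, c(trials[cellcols], sep = "\r"))
    mu <- tapply(trials$rt_ms[surv], cell[surv], mean)
    s <- tapply(trials$rt_ms[surv], cell[surv], sd)
    z_ok <- rep(TRUE, nrow(trials))
    known <- cell %in% names(mu)
    dev <- abs(trials$rt_ms - unname(mu[cell]))
    lim <- config$sd_cutoff * unname(s[cell])
    # single-trial cells have SD NA: nothing to remove there
    z_ok <- is.na(lim) | dev <= lim | !known
    hit(surv & !z_ok, "sd_outlier")
  }

  retained <- trials[is.na(rule), , drop = FALSE]

  # per-participant per-rule counts, zeros kept so logs stay additive
  pids <- sort(unique(trials$participant_id))
  excl <- expand.grid(participant_id = pids, rule = .filter_rules,
                      stringsAsFactors = FALSE)
  tab <- table(trials$participant_id[!is.na(rule)], rule[!is.na(rule)])
  excl$n_removed <- mapply(function(p, r) {
    if (p %in% rownames(tab) && r %in% colnames(tab)) tab[p, r] else 0L
  }, excl$participant_id, excl$rule)
  excl <- tibble::as_tibble(excl[order(excl$participant_id), ])

  cellcount <- table(retained$participant_id, retained$congruency)
  low <- rownames(cellcount)[apply(cellcount, 1, function(x) any(x < 2)) |
                               ncol(cellcount) < 2]
  retained$low_trial <- retained$participant_id %in% low

  list(retained = tibble::as_tibble(retained), exclusions = excl)
}

#' Natural-log transform of measure columns
#'
#' Applies `log()` to the selected measure columns (in ms); downstream
#' congruency effects then become differences of log-means. All values must
#' be strictly positive.
#'
#' @param trials trial tibble.
#' @param measures character vector of column names to transform, e.g.
#'   `c("rt_ms", "it_ms", "mt_ms")`.
#' @return The tibble with the named columns replaced by their natural logs.
#' @export
log_transform <- function(trials, measures = c("rt_ms", "it_ms", "mt_ms")) {
  miss <- setdiff(measures, names(trials))
  if (length(miss) > 0) {
    stop("log_transform: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (m in measures) {
    v <- trials[[m]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad) > 0) {
      stop("log_transform: nonpositive ", m, " at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    trials[[m]] <- log(v)
  }
  trials
}
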