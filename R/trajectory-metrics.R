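#' Reach trajectory container
#'
#' Time-stamped position samples for one trial's reach. Sample times must be
#' strictly increasing, at least 3 samples are required, and the end point
#' (target contact) must coincide with the last sample. Positions are in mm;
#' 2-D and 3-D trajectories are both supported (`z_mm` optional, default 0).
#'
#' @param samples a data frame with columns `t_ms`, `x_mm`, `y_mm`, and
#'   optionally `z_mm`.
#' @param start_point numeric position (length 2 or 3) of the starting
#'   location.
#' @param end_point numeric position of the selected target; defaults to the
#'   last sample's position.
#' @param trial_uid optional trial identifier.
#' @return An object of class `reach_trajectory`.
#' @export
reach_trajectory <- function(samples, start_point, end_point = NULL,
                             trial_uid = NA_character_) {
  samples <- tibble::as_tibble(samples)
  need <- c("t_ms", "x_mm", "y_mm")
  if (!all(need %in% names(samples))) {
    stop("trajectory samples need columns t_ms, x_mm, y_mm", call. = FALSE)
  }
  if (!"z_mm" %in% names(samples)) samples$z_mm <- 0
  if (nrow(samples) < 3) {
    stop("a trajectory needs at least 3 samples", call. = FALSE)
  }
  if (any(diff(samples$t_ms) <= 0)) {
    stop("trajectory sample times must be strictly increasing", call. = FALSE)
  }
  start_point <- pad3(start_point)
  last <- as.numeric(samples[nrow(samples), c("x_mm", "y_mm", "z_mm")])
  if (is.null(end_point)) {
    end_point <- last
  } else {
    end_point <- pad3(end_point)
    if (max(abs(end_point - last)) > 1e-6) {
      stop("end_point must equal the final sample's position", call. = FALSE)
    }
  }
  structure(
    list(samples = samples, start_point = start_point, end_point = end_point,
         trial_uid = trial_uid),
    class = "reach_trajectory"
  )
}

pad3 <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 2) p <- c(p, 0)
  if (length(p) != 3 || any(!is.finite(p))) {
    stop("positions must be finite length-2 or length-3 numeric", call. = FALSE)
  }
  p
}

#' @export
print.reach_trajectory <- function(x, ...) {
  cat(sprintf("<reach_trajectory> %d samples, %.0f-%.0f ms\n",
              nrow(x$samples), min(x$samples$t_ms), max(x$samples$t_ms)))
  invisible(x)
}

traj_positions <- function(trajectory) {
  as.matrix(trajectory$samples[, c("x_mm", "y_mm", "z_mm")])
}

#' Detect movement onset from a trajectory
#'
#' Movement onset is the time of the first sample (at or after stimulus
#' onset) whose Euclidean displacement from the start point exceeds the
#' displacement threshold. A displacement criterion is used rather than a
#' velocity criterion; the default threshold is 5 mm.
#'
#' @param trajectory a [reach_trajectory()].
#' @param stimulus_onset stimulus onset time in ms (same clock as `t_ms`).
#' @param displacement_threshold threshold in mm; must be > 0.
#' @return Onset time in ms.
#' @export
#' @examples
#' tr <- synthesize_trajectory(it = 300, mt = 400, response_side = "R",
#'                             onset_jitter_sd = 0)
#' detect_movement_onset(tr)
detect_movement_onset <- function(trajectory, stimulus_onset = 0,
                                  displacement_threshold = 5) {
  stopifnot(inherits(trajectory, "reach_trajectory"),
            displacement_threshold > 0)
  s <- trajectory$samples
  pos <- traj_positions(trajectory)
  disp <- sqrt(colSums((t(pos) - trajectory$start_point)^2))
  ok <- s$t_ms >= stimulus_onset & disp > displacement_threshold
  if (!any(ok)) {
    stop("no movement detected: no sample exceeds the displacement threshold",
         call. = FALSE)
  }
  s$t_ms[which(ok)[1]]
}

#' Reach curvature of a trajectory
#'
#' Curvature (CURV) is the length of the maximum deviation of the observed
#' trajectory from the direct trajectory, divided by the length of the
#' direct trajectory. The deviation of each post-onset sample is its
#' perpendicular distance to the infinite line through the onset position
#' and the end point (not the segment); the direct length is the Euclidean
#' onset-to-end distance. CURV is unitless and >= 0.
#'
#' @param trajectory a [reach_trajectory()].
#' @param onset_time movement onset in ms, e.g. from
#'   [detect_movement_onset()].
#' @return Curvature ratio.
#' @export
compute_curvature <- function(trajectory, onset_time) {
  stopifnot(inherits(trajectory, "reach_trajectory"))
  s <- trajectory$samples
  if (onset_time >= max(s$t_ms)) {
    stop("onset_time must precede the final sample", call. = FALSE)
  }
  keep <- s$t_ms >= onset_time
  pos <- traj_positions(trajectory)[keep, , drop = FALSE]
  origin <- pos[1, ]
  d <- trajectory$end_point - origin
  len <- sqrt(sum(d^2))
  if (len <= 0) {
    stop("degenerate geometry: direct path has zero length", call. = FALSE)
  }
  u <- d / len
  rel <- t(pos) - origin
  along <- colSums(rel * u)
  perp2 <- pmax(colSums(rel^2) - along^2, 0)
  max(sqrt(perp2)) / len
}

#' Extract IT, MT, RT, and CURV for one trial
#'
#' From a raw trajectory: IT is the time from stimulus onset to movement
#' onset, MT from movement onset to response completion, RT their sum, and
#' CURV from [compute_curvature()]. For release-and-press data (no
#' trajectory), pass `release_time` and `press_time` instead and CURV is
#' absent (`NA`).
#'
#' @param trajectory a [reach_trajectory()], or `NULL` for release-and-press
#'   records.
#' @param stimulus_onset stimulus onset time in ms.
#' @param response_completion_time target contact / key press time in ms;
#'   defaults to the trajectory's last sample time.
#' @param displacement_threshold onset threshold in mm.
#' @param release_time,press_time release-and-press timestamps (ms), used
#'   when no trajectory is available.
#' @return A one-row tibble `it_ms`, `mt_ms`, `rt_ms`, `curv`.
#' @export
extract_measures <- function(trajectory = NULL, stimulus_onset = 0,
                             response_completion_time = NULL,
                             displacement_threshold = 5,
                             release_time = NULL, press_time = NULL) {
  if (is.null(trajectory)) {
    if (is.null(release_time) || is.null(press_time)) {
      stop("without a trajectory, release_time and press_time are required",
           call. = FALSE)
    }
    if (press_time <= stimulus_onset || release_time < stimulus_onset ||
        press_time < release_time) {
      stop("release-and-press timestamps out of order", call. = FALSE)
    }
    return(tibble::tibble(
      it_ms = release_time - stimulus_onset,
      mt_ms = press_time - release_time,
      rt_ms = press_time - stimulus_onset,
      curv = NA_real_
    ))
  }
  if (is.null(response_completion_time)) {
    response_completion_time <- max(trajectory$samples$t_ms)
  }
  if (response_completion_time <= stimulus_onset) {
    stop("response_completion_time must exceed stimulus_onset", call. = FALSE)
  }
  onset <- detect_movement_onset(trajectory, stimulus_onset,
                                 displacement_threshold)
  tibble::tibble(
    it_ms = onset - stimulus_onset,
    mt_ms = response_completion_time - onset,
    rt_ms = response_completion_time - stimulus_onset,
    curv = compute_curvature(trajectory, onset)
  )
}

#' Extract measures for a whole trajectory store
#'
#' Applies [extract_measures()] to every trial in a long trajectory table
#' (columns `trial_uid`, `t_ms`, `x_mm`, `y_mm`, optionally `z_mm`). Trials
#' where onset detection fails are flagged rather than dropped.
#'
#' @param trajectories long trajectory tibble.
#' @param start_points optional tibble `trial_uid`, `x_mm`, `y_mm` (and
#'   `z_mm`) of per-trial start points; defaults to each trial's first
#'   sample.
#' @param stimulus_onset,displacement_threshold as in [extract_measures()].
#' @return A tibble with one row per trial: `trial_uid`, `it_ms`, `mt_ms`,
#'   `rt_ms`, `curv`, `measure_ok`, `measure_note`.
#' @export
extract_measures_batch <- function(trajectories, start_points = NULL,
                                   stimulus_onset = 0,
                                   displacement_threshold = 5) {
  stopifnot(all(c("trial_uid", "t_ms", "x_mm", "y_mm") %in% names(trajectories)))
  uids <- unique(trajectories$trial_uid)
  sp <- NULL
  if (!is.null(start_points)) {
    sp <- as.data.frame(start_points)
    rownames(sp) <- sp$trial_uid
  }
  rows <- lapply(uids, function(uid) {
    s <- trajectories[trajectories$trial_uid == uid, , drop = FALSE]
    start <- if (is.null(sp)) {
      as.numeric(s[1, intersect(c("x_mm", "y_mm", "z_mm"), names(s))])
    } else {
      as.numeric(sp[uid, intersect(c("x_mm", "y_mm", "z_mm"), names(sp))])
    }
    res <- tryCatch({
      tr <- reach_trajectory(s[, setdiff(names(s), "trial_uid")], start,
                             trial_uid = uid)
      m <- extract_measures(tr, stimulus_onset = stimulus_onset,
                            displacement_threshold = displacement_threshold)
      cbind(tibble::tibble(trial_uid = uid), m,
            tibble::tibble(measure_ok = TRUE, measure_note = NA_character_))
    }, error = function(e) {
      tibble::tibble(trial_uid = uid, it_ms = NA_real_, mt_ms = NA_real_,
                     rt_ms = NA_real_, curv = NA_real_, measure_ok = FALSE,
                     measure_note = conditionMessage(e))
    })
    res
  })
  tibble::as_tibble(dplyr::bind_rows(rows))
}
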