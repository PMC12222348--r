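#' Draw per-participant random effects
#'
#' Realizes one set of participant-level coefficients per participant from
#' the normal between-participant distributions in the config. Uses the
#' current RNG state; [simulate_dataset()] seeds the RNG from `config$seed`
#' before calling this.
#'
#' @param config a validated [sim_config()].
#' @return A tibble with one row per participant: baselines, effect
#'   coefficients, and error/partial-error probabilities.
#' @export
sample_participant_effects <- function(config) {
  validate_sim_config(config)
  n <- config$n_participants
  tibble::tibble(
    participant_id = sprintf("p%03d", seq_len(n)),
    it_baseline = rnorm(n, config$it_baseline_mean, config$it_baseline_sd),
    mt_baseline = rnorm(n, config$mt_baseline_mean, config$mt_baseline_sd),
    it_congruency = rnorm(n, config$it_congruency_mean, config$it_congruency_sd),
    it_prev_congruency = rnorm(n, config$it_prev_congruency_mean,
                               config$it_prev_congruency_sd),
    mt_congruency = rnorm(n, config$mt_congruency_mean, config$mt_congruency_sd),
    mt_cIr_boost = rnorm(n, config$mt_cIr_boost_mean, config$mt_cIr_boost_sd),
    partial_error_prob_incongruent = config$partial_error_prob_incongruent,
    partial_error_prob_congruent = config$partial_error_prob_congruent,
    overt_error_prob_incongruent = config$overt_error_prob_incongruent,
    overt_error_prob_congruent = config$overt_error_prob_congruent
  )
}

# normal draws resampled until all >= lo (times must stay positive)
truncated_normal <- function(n, mean, sd, lo = 1) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo)
  guard <- 0L
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), if (length(mean) > 1) mean[bad] else mean,
                    if (length(sd) > 1) sd[bad] else sd)
    bad <- bad[x[bad] < lo]
    guard <- guard + 1L
    if (guard > 10000L) { # pathological config; clamp rather than spin
      x[bad] <- lo
      break
    }
  }
  x
}

#' Simulate a trial-level congruency-task dataset
#'
#' Generates the full trial table (and, in trajectory mode, raw reach
#' trajectories for every trial) under the dual-process generative model
#' described in [sim_config()]: current-trial and previous-trial congruency
#' effects on IT, a current-congruency effect plus a cI-r
#' (congruent-preceding-incongruent, response-repetition) slowing on MT, a
#' correction cost on partial-error trials, rare overt errors, and block
#' structure. Congruency (half congruent, half incongruent) is randomized
#' within block; target side is random, so response repetitions arise at
#' about 50%. All times are truncated below at 1 ms by resampling. The same
#' config (including seed) always yields the identical dataset.
#'
#' @param config a [sim_config()].
#' @return In summary mode, a trial tibble with columns `participant_id`,
#'   `age_group`, `condition_id`, `block`, `trial_index`, `congruency`
#'   (`"C"`/`"I"`), `target_side`, `response_side` (`"L"`/`"R"`), `accuracy`
#'   (`"correct"`/`"error"`), `partial_error`, `it_ms`, `mt_ms`, `rt_ms`. In
#'   trajectory mode, a list with elements `trials` (that tibble) and
#'   `trajectories` (a long tibble `trial_uid`, `t_ms`, `x_mm`, `y_mm`); the
#'   trial table gains a `trial_uid` key in both modes.
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  params <- sample_participant_effects(config)
  nb <- config$n_blocks
  tpb <- config$trials_per_block

  one_participant <- function(i) {
    p <- params[i, ]
    blocks <- lapply(seq_len(nb), function(b) {
      cong <- sample(rep(c("C", "I"), each = tpb / 2))
      target <- sample(c("L", "R"), tpb, replace = TRUE)
      is_i <- cong == "I"
      err_p <- ifelse(is_i, p$overt_error_prob_incongruent,
                      p$overt_error_prob_congruent)
      error <- runif(tpb) < err_p
      response <- ifelse(error, ifelse(target == "L", "R", "L"), target)
      part_p <- ifelse(is_i, p$partial_error_prob_incongruent,
                       p$partial_error_prob_congruent)
      partial <- runif(tpb) < part_p & !error
      commit <- pmin(pmax(rnorm(tpb, config$commitment_fraction_mean,
                                config$commitment_fraction_sd), 0.01), 0.99)
      commit[!partial] <- NA_real_

      prev_i <- c(FALSE, is_i[-tpb])
      prev_i[1] <- FALSE
      rep_resp <- c(FALSE, response[-1] == response[-tpb])
      first <- seq_len(tpb) == 1L
      cIr <- is_i & !prev_i & rep_resp & !first

      it_mu <- p$it_baseline + p$it_congruency * is_i +
        p$it_prev_congruency * ifelse(first, 0, prev_i)
      mt_mu <- p$mt_baseline + p$mt_congruency * is_i +
        p$mt_cIr_boost * cIr +
        ifelse(partial, commit * config$mt_correction_cost, 0)
      it <- truncated_normal(tpb, it_mu, config$it_noise_sd)
      mt <- truncated_normal(tpb, mt_mu, config$mt_noise_sd)

      tibble::tibble(
        participant_id = p$participant_id,
        age_group = config$age_group,
        condition_id = config$condition_id,
        block = b,
        trial_index = seq_len(tpb),
        congruency = cong,
        target_side = target,
        response_side = response,
        accuracy = ifelse(error, "error", "correct"),
        partial_error = partial,
        commitment_fraction = commit,
        it_ms = it,
        mt_ms = mt,
        rt_ms = it + mt
      )
    })
    dplyr::bind_rows(blocks)
  }

  trials <- dplyr::bind_rows(lapply(seq_len(config$n_participants),
                                    one_participant))
  trials$trial_uid <- sprintf("%s_b%02d_t%03d", trials$participant_id,
                              trials$block, trials$trial_index)
  trials <- dplyr::relocate(trials, "trial_uid")

  if (config$mode == "summary") {
    return(trials)
  }

  geom <- list(start = config$start_point, left = config$target_left,
               right = config$target_right)
  trajs <- vector("list", nrow(trials))
  for (k in seq_len(nrow(trials))) {
    tr <- trials[k, ]
    traj <- synthesize_trajectory(
      it = tr$it_ms, mt = tr$mt_ms,
      response_side = tr$response_side,
      partial_error = tr$partial_error,
      commitment_fraction = tr$commitment_fraction,
      geometry = geom,
      sampling_rate = config$sampling_rate,
      onset_jitter_sd = config$onset_jitter_sd
    )
    s <- traj$samples
    s$trial_uid <- tr$trial_uid
    trajs[[k]] <- s
  }
  trajectories <- dplyr::relocate(dplyr::bind_rows(trajs), "trial_uid")
  list(trials = trials, trajectories = trajectories)
}

#' Synthesize one reach trajectory
#'
#' Builds the time-stamped position samples for a single trial from its
#' realized IT and MT. Before movement onset the position sits at the start
#' point plus Gaussian jitter; from onset the hand travels to the responded
#' target — directly (with small lateral jitter) on ordinary trials, or
#' toward the opposite target for `commitment_fraction` of the movement and
#' then smoothly redirected on partial-error trials. The final sample is
#' placed exactly at the responded target at time `it + mt`.
#'
#' @param it,mt initiation and movement time in ms.
#' @param response_side `"L"` or `"R"` — the target actually contacted.
#' @param partial_error logical; did the reach start toward the wrong target?
#' @param commitment_fraction fraction of MT initially spent heading to the
#'   wrong target (partial-error trials only).
#' @param geometry list with numeric length-2 points `start`, `left`, `right`
#'   (mm).
#' @param sampling_rate sampling rate in Hz.
#' @param onset_jitter_sd positional jitter SD in mm (0 gives ideal paths).
#' @return A `reach_trajectory` object (see [reach_trajectory()]).
#' @export
synthesize_trajectory <- function(it, mt, response_side,
                                  partial_error = FALSE,
                                  commitment_fraction = NA_real_,
                                  geometry = list(start = c(0, 0),
                                                  left = c(-100, 280),
                                                  right = c(100, 280)),
                                  sampling_rate = 100,
                                  onset_jitter_sd = 0.5) {
  stopifnot(is.finite(it), is.finite(mt), it >= 0, mt > 0)
  start <- as.numeric(geometry$start)
  target <- as.numeric(if (response_side == "L") geometry$left else geometry$right)
  wrong <- as.numeric(if (response_side == "L") geometry$right else geometry$left)
  if (all(start == target)) {
    stop("degenerate geometry: start point equals the target", call. = FALSE)
  }

  dt <- 1000 / sampling_rate
  # sample clock re-synchronises at movement onset, so the first post-onset
  # sample lies exactly one period into the movement and threshold-based
  # onset detection lands within one sample period of the generating IT
  t_pre <- seq(0, it, by = dt)
  t_pre <- t_pre[t_pre < it]
  t_mov <- seq(it, it + mt, by = dt)
  if (t_mov[length(t_mov)] < it + mt) t_mov <- c(t_mov, it + mt)
  t <- c(t_pre, t_mov)
  n <- length(t)
  pre <- t < it
  u <- pmax(0, pmin(1, (t - it) / mt))

  pos <- matrix(0, n, 2)
  pos[pre, 1] <- start[1]
  pos[pre, 2] <- start[2]
  mov <- !pre
  if (isTRUE(partial_error)) {
    f <- commitment_fraction
    if (!is.finite(f) || f <= 0 || f >= 1) {
      stop("partial-error trajectory needs commitment_fraction in (0, 1)",
           call. = FALSE)
    }
    turn <- start + f * (wrong - start)
    phase1 <- mov & u <= f
    phase2 <- mov & u > f
    pos[phase1, ] <- start[col(pos[phase1, , drop = FALSE])] +
      outer(u[phase1], wrong - start)
    s <- (u[phase2] - f) / (1 - f)
    s <- 3 * s^2 - 2 * s^3 # smoothstep redirection
    pos[phase2, ] <- turn[col(pos[phase2, , drop = FALSE])] +
      outer(s, target - turn)
  } else {
    pos[mov, ] <- start[col(pos[mov, , drop = FALSE])] +
      outer(u[mov], target - start)
  }

  if (onset_jitter_sd > 0) {
    # jitter pre-onset isotropically, in-flight only laterally
    pos[pre, ] <- pos[pre, ] + rnorm(2 * sum(pre), 0, onset_jitter_sd)
    dir <- target - start
    perp <- c(-dir[2], dir[1]) / sqrt(sum(dir^2))
    lat <- rnorm(sum(mov), 0, onset_jitter_sd)
    pos[mov, ] <- pos[mov, ] + outer(lat, perp)
  }
  pos[n, ] <- target # response completion: contact with the target

  reach_trajectory(
    samples = tibble::tibble(t_ms = t, x_mm = pos[, 1], y_mm = pos[, 2]),
    start_point = start,
    end_point = target
  )
}

#' Closed-form true reliability of simulated congruency effects
#'
#' For the generative model in [sim_config()], the congruency-effect
#' difference score of participant *i* is their effect coefficient plus
#' mean-of-noise terms, so its full-length reliability has the classical
#' variance-components form
#' \deqn{\rho = \tau^2 / (\tau^2 + \sigma^2 (1/n_C + 1/n_I))}
#' with \eqn{\tau^2} the between-participant variance of the effect
#' coefficient and \eqn{\sigma^2} the within-participant trial-noise
#' variance. This is the quantity the permutation split-half estimator
#' targets after Spearman-Brown correction. For MT the cI-r slowing loads on
#' a quarter of incongruent trials, contributing \eqn{\tau^2_{boost}/16};
#' for RT the IT and MT components add. Partial-error correction costs are
#' ignored (negligible at default rates) and noted in the vignette.
#'
#' @param config a [sim_config()].
#' @param n_retained_per_condition expected retained trials per congruency
#'   cell per participant (scalar, or length-2 `c(n_C, n_I)`).
#' @return A tibble with `measure` (`it`, `mt`, `rt`), `tau2`, `sigma2`, and
#'   `reliability`.
#' @seealso [reliability_from_components()] for the bare identity.
#' @export
true_reliability <- function(config, n_retained_per_condition) {
  validate_sim_config(config)
  n <- n_retained_per_condition
  if (length(n) == 1) n <- c(n, n)
  if (any(n < 1)) stop("n_retained_per_condition must be >= 1", call. = FALSE)
  tau2 <- c(
    it = config$it_congruency_sd^2,
    mt = config$mt_congruency_sd^2 + config$mt_cIr_boost_sd^2 / 16
  )
  tau2 <- c(tau2, rt = unname(tau2["it"] + tau2["mt"]))
  sigma2 <- c(
    it = config$it_noise_sd^2,
    mt = config$mt_noise_sd^2
  )
  sigma2 <- c(sigma2, rt = unname(sigma2["it"] + sigma2["mt"]))
  rel <- vapply(c("it", "mt", "rt"), function(m) {
    reliability_from_components(tau2[m], sigma2[m], n[1], n[2])
  }, numeric(1))
  tibble::tibble(
    measure = c("it", "mt", "rt"),
    tau2 = unname(tau2[c("it", "mt", "rt")]),
    sigma2 = unname(sigma2[c("it", "mt", "rt")]),
    reliability = unname(rel[c("it", "mt", "rt")])
  )
}

#' Variance-components reliability of a two-condition difference score
#'
#' @param tau2 between-participant variance of the true effect.
#' @param sigma2 within-participant trial-noise variance.
#' @param n_c,n_i trials per congruent / incongruent cell.
#' @return `tau2 / (tau2 + sigma2 * (1/n_c + 1/n_i))`.
#' @export
#' @examples
#' reliability_from_components(36^2, 60^2, 80, 80) # 0.935
reliability_from_components <- function(tau2, sigma2, n_c, n_i) {
  stopifnot(tau2 >= 0, sigma2 >= 0, n_c >= 1, n_i >= 1)
  if (tau2 == 0 && sigma2 == 0) {
    stop("reliability undefined: tau2 and sigma2 are both zero", call. = FALSE)
  }
  tau2 / (tau2 + sigma2 * (1 / n_c + 1 / n_i))
}
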