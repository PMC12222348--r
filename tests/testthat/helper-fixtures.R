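# Shared fixtures and independent oracles. Everything here is deliberately
# naive (loops, brute force) so it stays independent of the package's
# vectorised implementations.

# config with every between/within variance source switched off
null_sim_config <- function(n_participants = 10, n_blocks = 2,
                            trials_per_block = 16, noise = 0, seed = 1) {
  sim_config(
    n_participants = n_participants, n_blocks = n_blocks,
    trials_per_block = trials_per_block,
    it_baseline_sd = 0, mt_baseline_sd = 0,
    it_congruency_mean = 0, it_congruency_sd = 0,
    it_prev_congruency_mean = 0, it_prev_congruency_sd = 0,
    mt_congruency_mean = 0, mt_congruency_sd = 0,
    mt_cIr_boost_mean = 0, mt_cIr_boost_sd = 0,
    it_noise_sd = noise, mt_noise_sd = noise,
    partial_error_prob_incongruent = 0, partial_error_prob_congruent = 0,
    overt_error_prob_incongruent = 0, overt_error_prob_congruent = 0,
    seed = seed
  )
}

# clean variance-components config for reliability recovery: IT carries
# tau/sigma, everything else off
recovery_sim_config <- function(tau, sigma, trials_per_block,
                                n_participants = 100, seed = 1) {
  sim_config(
    n_participants = n_participants, n_blocks = 2,
    trials_per_block = trials_per_block,
    it_congruency_mean = 30, it_congruency_sd = tau,
    it_prev_congruency_mean = 0, it_prev_congruency_sd = 0,
    mt_cIr_boost_mean = 0, mt_cIr_boost_sd = 0,
    it_noise_sd = sigma, mt_noise_sd = sigma,
    partial_error_prob_incongruent = 0, partial_error_prob_congruent = 0,
    overt_error_prob_incongruent = 0, overt_error_prob_congruent = 0,
    seed = seed
  )
}

# hand-built trial table: one participant, values supplied directly
make_trials <- function(congruency, response_side = NULL, accuracy = NULL,
                        rt = NULL, it = NULL, mt = NULL,
                        participant_id = "p1", block = 1,
                        age_group = "adult") {
  n <- length(congruency)
  if (is.null(response_side)) response_side <- rep("L", n)
  if (is.null(accuracy)) accuracy <- rep("correct", n)
  if (is.null(it)) it <- rep(300, n)
  if (is.null(mt)) mt <- rep(300, n)
  if (is.null(rt)) rt <- it + mt
  tibble::tibble(
    participant_id = participant_id, age_group = age_group,
    condition_id = "lab", block = block, trial_index = seq_len(n),
    congruency = congruency, target_side = response_side,
    response_side = response_side, accuracy = accuracy,
    it_ms = it, mt_ms = mt, rt_ms = rt
  )
}

# multi-participant table with known per-cell trial values
make_cell_trials <- function(values_c, values_i) {
  stopifnot(length(values_c) == length(values_i))
  rows <- lapply(seq_along(values_c), function(i) {
    vc <- values_c[[i]]
    vi <- values_i[[i]]
    tibble::tibble(
      participant_id = sprintf("p%02d", i), age_group = "adult",
      condition_id = "lab", block = 1,
      trial_index = seq_len(length(vc) + length(vi)),
      congruency = c(rep("C", length(vc)), rep("I", length(vi))),
      target_side = "L", response_side = "L", accuracy = "correct",
      it_ms = c(vc, vi), mt_ms = 1, rt_ms = c(vc, vi) + 1
    )
  })
  dplyr::bind_rows(rows)
}

# naive split-half: independent loop-based reimplementation of one random
# difference-score split (floor/ceil halves, Pearson r, Spearman-Brown)
naive_split_half <- function(trials, measure_col = "it_ms") {
  pids <- unique(trials$participant_id)
  s1 <- s2 <- numeric(length(pids))
  for (k in seq_along(pids)) {
    half_means <- list()
    for (cg in c("C", "I")) {
      v <- trials[[measure_col]][trials$participant_id == pids[k] &
                                   trials$congruency == cg]
      idx <- sample(length(v))
      h <- floor(length(v) / 2)
      half_means[[cg]] <- c(mean(v[idx[seq_len(h)]]), mean(v[idx[-seq_len(h)]]))
    }
    s1[k] <- half_means[["I"]][1] - half_means[["C"]][1]
    s2[k] <- half_means[["I"]][2] - half_means[["C"]][2]
  }
  r <- cor(s1, s2)
  2 * r / (1 + r)
}

# exact expectation of the split-half r_sb for 2 trials per cell by full
# enumeration of all joint half assignments (2 per cell)
enumerate_split_half_2per <- function(trials, measure_col = "it_ms") {
  pids <- unique(trials$participant_id)
  np <- length(pids)
  vals <- array(NA_real_, c(np, 2, 2)) # participant x cong(C=1,I=2) x trial
  for (k in seq_along(pids)) {
    for (cg in 1:2) {
      v <- trials[[measure_col]][trials$participant_id == pids[k] &
                                   trials$congruency == c("C", "I")[cg]]
      stopifnot(length(v) == 2)
      vals[k, cg, ] <- v
    }
  }
  nbits <- 2 * np
  total <- 0
  count <- 0
  for (code in 0:(2^nbits - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(nbits)]
    s1 <- s2 <- numeric(np)
    for (k in seq_len(np)) {
      bc <- bits[2 * k - 1] + 1L # which C trial is half1
      bi <- bits[2 * k] + 1L
      s1[k] <- vals[k, 2, bi] - vals[k, 1, bc]
      s2[k] <- vals[k, 2, 3 - bi] - vals[k, 1, 3 - bc]
    }
    r <- suppressWarnings(cor(s1, s2))
    if (!is.na(r) && r > -1) {
      total <- total + 2 * r / (1 + r)
      count <- count + 1
    }
  }
  total / count
}

# independent RM-ANOVA oracle via stats::aov with Error strata
aov_oracle <- function(cellmeans) {
  cm <- cellmeans[cellmeans$complete, ]
  cm$pid <- factor(cm$participant_id)
  cm$A <- factor(cm$congruency_n)
  cm$B <- factor(cm$prev_congruency)
  cm$C <- factor(cm$response_repetition)
  fit <- stats::aov(cell_mean ~ A * B * C + Error(pid / (A * B * C)),
                    data = cm)
  s <- summary(fit)
  fs <- c()
  for (stratum in s) {
    tab <- stratum[[1]]
    eff <- rownames(tab)
    for (j in seq_along(eff)) {
      nm <- gsub(" ", "", eff[j])
      if (nm != "Residuals") fs[nm] <- tab[j, "F value"]
    }
  }
  fs
}

# deterministic cell-means table from an N x 8 matrix (cells in the package's
# sorted order: C/I x c/i x alternation/repetition)
cellmeans_from_matrix <- function(m) {
  key <- expand.grid(response_repetition = c("alternation", "repetition"),
                     prev_congruency = c("c", "i"),
                     congruency_n = c("C", "I"),
                     stringsAsFactors = FALSE)
  key <- key[, c("congruency_n", "prev_congruency", "response_repetition")]
  rows <- lapply(seq_len(nrow(m)), function(i) {
    tibble::tibble(participant_id = sprintf("p%02d", i), measure = "it",
                   congruency_n = key$congruency_n,
                   prev_congruency = key$prev_congruency,
                   response_repetition = key$response_repetition,
                   cell_mean = m[i, ], n_trials = 5L, complete = TRUE)
  })
  dplyr::arrange(dplyr::bind_rows(rows), participant_id, congruency_n,
                 prev_congruency, response_repetition)
}
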