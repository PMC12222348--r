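test_that("a single-trial block gets none codes", {
  tr <- code_conditions(make_trials("C"))
  expect_equal(tr$prev_congruency, "none")
  expect_equal(tr$response_repetition, "none")
  expect_true(tr$first_of_block)
  expect_false(tr$post_error)
})

test_that("sequence coding follows the immediately preceding trial", {
  tr <- code_conditions(make_trials(c("C", "I"), response_side = c("L", "L")))
  expect_equal(tr$prev_congruency[2], "c")
  expect_equal(tr$response_repetition[2], "repetition")

  tr2 <- code_conditions(make_trials(c("I", "C"),
                                     response_side = c("L", "R"),
                                     accuracy = c("error", "correct")))
  expect_equal(tr2$prev_congruency[2], "i")
  expect_equal(tr2$response_repetition[2], "alternation")
  expect_true(tr2$post_error[2])
})

test_that("coding matches a brute-force re-derivation on a randomized block", {
  set.seed(404)
  n <- 48
  raw <- make_trials(sample(rep(c("C", "I"), each = n / 2)),
                     response_side = sample(c("L", "R"), n, replace = TRUE),
                     accuracy = sample(c("correct", "error"), n,
                                       replace = TRUE, prob = c(0.9, 0.1)))
  coded <- code_conditions(raw)
  for (k in seq_len(n)) {
    if (k == 1) {
      expect_equal(coded$prev_congruency[k], "none")
      expect_equal(coded$response_repetition[k], "none")
      expect_false(coded$post_error[k])
    } else {
      expect_equal(coded$prev_congruency[k], tolower(raw$congruency[k - 1]))
      expect_equal(coded$response_repetition[k],
                   ifelse(raw$response_side[k] == raw$response_side[k - 1],
                          "repetition", "alternation"))
      expect_equal(coded$post_error[k], raw$accuracy[k - 1] == "error")
    }
  }
})

test_that("sequence codes never cross a block boundary", {
  b1 <- make_trials(c("C", "I"), block = 1)
  b2 <- make_trials(c("I", "C"), block = 2)
  coded <- code_conditions(dplyr::bind_rows(b1, b2))
  expect_equal(coded$prev_congruency[coded$block == 2],
               c("none", "i"))
  expect_equal(sum(coded$first_of_block), 2)
})

test_that("duplicate trial keys are rejected", {
  dup <- dplyr::bind_rows(make_trials("C"), make_trials("C"))
  expect_error(code_conditions(dup), "duplicate")
})

test_that("hand-enumerated toy block reproduces the exclusion ladder", {
  # 10 trials: trial 1 first-of-block, trial 4 an error, trial 5 post-error,
  # trial 8 has RT = 150 ms (< 200) -> 6 retained
  tr <- make_trials(rep(c("C", "I"), 5),
                    accuracy = c("correct", "correct", "correct", "error",
                                 rep("correct", 6)),
                    rt = c(600, 610, 620, 630, 640, 650, 660, 150, 680, 690))
  f <- filter_trials(code_conditions(tr))
  expect_equal(nrow(f$retained), 6)
  counts <- setNames(f$exclusions$n_removed, f$exclusions$rule)
  expect_equal(unname(counts[c("first_of_block", "error", "post_error",
                               "rt_bounds", "sd_outlier")]),
               c(1, 1, 1, 1, 0))
})

test_that("each trial is attributed to the first rule that catches it", {
  # the first trial is also an error and out of bounds: counts as first_of_block
  tr <- make_trials(c("C", "I", "C", "I"),
                    accuracy = c("error", "correct", "correct", "correct"),
                    rt = c(5000, 600, 610, 620))
  f <- filter_trials(code_conditions(tr))
  counts <- setNames(f$exclusions$n_removed, f$exclusions$rule)
  expect_equal(unname(counts["first_of_block"]), 1)
  expect_equal(unname(counts["error"]), 0)
  expect_equal(unname(counts["post_error"]), 1) # trial 2 follows the error
  expect_equal(unname(counts["rt_bounds"]), 0)
})

test_that("identical in-bounds RTs lose only the first-of-block trial", {
  tr <- make_trials(rep(c("C", "I"), 6), rt = rep(500, 12))
  f <- filter_trials(code_conditions(tr))
  expect_equal(nrow(f$retained), 11)
  counts <- setNames(f$exclusions$n_removed, f$exclusions$rule)
  expect_equal(unname(counts["sd_outlier"]), 0) # SD = 0 removes nothing
})

test_that("RT bounds depend on age group: 3000 ms excluded for adults only", {
  adult <- make_trials(rep(c("C", "I"), 4),
                       rt = c(600, 620, 3000, 640, 660, 680, 700, 720))
  child <- adult
  child$age_group <- "child"
  fa <- filter_trials(code_conditions(adult))
  fc <- filter_trials(code_conditions(child))
  expect_false(3000 %in% fa$retained$rt_ms)
  expect_true(3000 %in% fc$retained$rt_ms)
})

test_that("SD rule removes extreme trials relative to the participant's own cell", {
  set.seed(8)
  rts <- c(rnorm(40, 600, 20), 2000) # still below the absolute bound
  tr <- make_trials(rep("C", 41), rt = rts)
  tr <- dplyr::bind_rows(tr, make_trials(rep("I", 4), rt = rep(600, 4),
                                         block = 2))
  f <- filter_trials(code_conditions(tr))
  counts <- setNames(f$exclusions$n_removed, f$exclusions$rule)
  expect_equal(unname(counts["sd_outlier"]), 1)
  expect_false(2000 %in% f$retained$rt_ms)
})

test_that("exclusion log is additive and filtering leaves values untouched", {
  cfg <- sim_config(n_participants = 8, n_blocks = 2, trials_per_block = 24,
                    overt_error_prob_incongruent = 0.1,
                    overt_error_prob_congruent = 0.05, seed = 31)
  tr <- code_conditions(simulate_dataset(cfg))
  f <- filter_trials(tr)
  per_part <- tapply(f$exclusions$n_removed, f$exclusions$participant_id, sum)
  kept <- table(f$retained$participant_id)
  for (p in unique(tr$participant_id)) {
    expect_equal(unname(per_part[p]) + unname(kept[p]),
                 sum(tr$participant_id == p))
  }
  expect_true(all(f$retained$trial_uid %in% tr$trial_uid))
  m <- match(f$retained$trial_uid, tr$trial_uid)
  expect_equal(f$retained$rt_ms, tr$rt_ms[m])
})

test_that("filtering is idempotent on in-bounds data without extreme outliers", {
  tr <- make_trials(rep(c("C", "I"), 10),
                    rt = rep(c(500, 520, 540, 560), 5))
  f1 <- filter_trials(code_conditions(tr))
  f2 <- filter_trials(f1$retained[setdiff(names(f1$retained), "low_trial")])
  expect_equal(nrow(f2$retained), nrow(f1$retained))
  expect_equal(sum(f2$exclusions$n_removed), 0)
})

test_that("a second filtering pass removes at most a negligible fraction", {
  # the single-pass 3-SD rule is not exactly idempotent: removing outliers
  # shrinks the recomputed SD, so a refilter can catch a stray trial
  cfg <- sim_config(n_participants = 10, n_blocks = 2, trials_per_block = 48,
                    seed = 77)
  tr <- code_conditions(simulate_dataset(cfg))
  f1 <- filter_trials(tr)
  f2 <- filter_trials(f1$retained[setdiff(names(f1$retained), "low_trial")])
  expect_lte(sum(f2$exclusions$n_removed), ceiling(0.005 * nrow(f1$retained)))
})

test_that("participants with sparse cells are flagged, not dropped", {
  tr <- dplyr::bind_rows(
    make_trials(rep(c("C", "I"), 6), participant_id = "rich"),
    make_trials(c("C", "C", "C", "I"), participant_id = "sparse")
  )
  f <- filter_trials(code_conditions(tr))
  expect_true(all(f$retained$low_trial[f$retained$participant_id == "sparse"]))
  expect_false(any(f$retained$low_trial[f$retained$participant_id == "rich"]))
})

test_that("log transform is natural log and rejects nonpositive values", {
  tr <- make_trials(c("C", "I"), rt = c(1000, 500))
  out <- log_transform(tr, "rt_ms")
  expect_equal(out$rt_ms[1], 6.9078, tolerance = 1e-4)
  bad <- make_trials(c("C", "I"), rt = c(1000, 500))
  bad$curv <- c(0, 0.1)
  expect_error(log_transform(bad, "curv"), "nonpositive")
})

test_that("log-scale congruency effects on default-like data are positive and below 1", {
  cfg <- sim_config(n_participants = 40, n_blocks = 2, trials_per_block = 48,
                    seed = 15)
  tr <- code_conditions(simulate_dataset(cfg))
  ret <- filter_trials(tr)$retained
  eff <- participant_condition_means(log_transform(ret, "rt_ms"), "rt")
  expect_gt(mean(eff$effect), 0)
  expect_lt(mean(eff$effect), 1)
})
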