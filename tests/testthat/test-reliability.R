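test_that("Spearman-Brown fixes 0 and 1 and matches hand arithmetic", {
  expect_equal(spearman_brown(0.5), 2 / 3)
  expect_equal(spearman_brown(1), 1)
  expect_equal(spearman_brown(0), 0)
  expect_equal(spearman_brown(-1 / 3), -1)
  expect_true(is.na(spearman_brown(-1)))
  r <- seq(-0.9, 1, by = 0.05)
  expect_true(all(diff(spearman_brown(r)) > 0)) # strictly increasing
})

test_that("reliability labels follow the conventional cutoffs with 2-dp rounding", {
  expect_equal(classify_reliability(0.69), "poor")
  expect_equal(classify_reliability(0.70), "acceptable")
  expect_equal(classify_reliability(0.794), "acceptable")
  expect_equal(classify_reliability(0.80), "good")
  expect_equal(classify_reliability(0.894), "good") # rounds to 0.89
  expect_equal(classify_reliability(0.896), "excellent") # rounds to 0.90
  expect_equal(classify_reliability(0.90), "excellent")
})

test_that("analytic difference-score identity matches hand arithmetic", {
  # reliable, strongly correlated components -> unreliable difference
  expect_equal(difference_score_reliability_analytic(0.9, 0.9, 0.8, 10, 10),
               0.5)
  # independent components -> variance-weighted mean of reliabilities
  expect_equal(difference_score_reliability_analytic(0.8, 0.6, 0, 3, 4),
               (0.8 * 9 + 0.6 * 16) / 25)
  expect_error(difference_score_reliability_analytic(0.9, 0.9, 1, 10, 10),
               "undefined")
})

test_that("noiseless measurement yields r_sb of exactly 1 on every split", {
  # trial values constant within participant-cell, effects vary between
  effs <- c(10, 40, 25, 60, 5, 35)
  tr <- make_cell_trials(
    lapply(seq_along(effs), function(i) rep(500 + 3 * i, 4)),
    lapply(seq_along(effs), function(i) rep(500 + 3 * i + effs[i], 4))
  )
  est <- permutation_reliability(tr, "it", n_permutations = 50, seed = 1)
  expect_equal(est$mean_r_sb, 1)
  expect_equal(est$ci_low, 1)
  expect_equal(est$n_invalid_splits, 0L)
})

test_that("two trials per cell (single-trial halves) runs without error", {
  set.seed(5)
  tr <- make_cell_trials(replicate(8, rnorm(2, 500, 30), simplify = FALSE),
                         replicate(8, rnorm(2, 560, 30), simplify = FALSE))
  est <- permutation_reliability(tr, "it", n_permutations = 100, seed = 2)
  expect_true(is.finite(est$mean_r_sb))
  expect_true(est$ci_low <= est$ci_high)
})

test_that("estimates are deterministic given a seed", {
  set.seed(6)
  tr <- make_cell_trials(replicate(10, rnorm(6, 500, 30), simplify = FALSE),
                         replicate(10, rnorm(6, 560, 40), simplify = FALSE))
  a <- permutation_reliability(tr, "it", n_permutations = 200, seed = 9)
  b <- permutation_reliability(tr, "it", n_permutations = 200, seed = 9)
  expect_identical(a, b)
})

test_that("participants below the trial minimum are dropped and counted", {
  set.seed(7)
  tr <- make_cell_trials(replicate(6, rnorm(4, 500, 30), simplify = FALSE),
                         replicate(6, rnorm(4, 560, 30), simplify = FALSE))
  sparse <- make_cell_trials(list(rnorm(1, 500, 30)), list(rnorm(4, 560, 30)))
  sparse$participant_id <- "p99"
  est <- permutation_reliability(dplyr::bind_rows(tr, sparse), "it",
                                 n_permutations = 50, seed = 3)
  expect_equal(est$n_participants_used, 6L)
  expect_equal(est$n_dropped_participants, 1L)
  expect_error(
    permutation_reliability(make_cell_trials(list(rnorm(4)), list(rnorm(4))),
                            "it", n_permutations = 10),
    "fewer than 3"
  )
})

test_that("permutation mean matches exact enumeration over all distinct splits", {
  # 6 participants x 2 trials per cell: the joint split space has 2^12
  # members; enumerate it fully for the exact expected r_sb
  set.seed(31)
  tr <- make_cell_trials(replicate(6, rnorm(2, 500, 30), simplify = FALSE),
                         replicate(6, rnorm(2, 560, 45), simplify = FALSE))
  exact <- enumerate_split_half_2per(tr, "it_ms")
  est <- permutation_reliability(tr, "it", n_permutations = 5000, seed = 17)
  r_sb <- attr(est, "r_sb")
  mc_se <- sd(r_sb, na.rm = TRUE) / sqrt(sum(!is.na(r_sb)))
  expect_lt(abs(est$mean_r_sb - exact), 3 * mc_se)
})

test_that("engine agrees with a naive loop-based split-half implementation", {
  set.seed(32)
  tr <- make_cell_trials(replicate(12, rnorm(4, 500, 30), simplify = FALSE),
                         replicate(12, rnorm(4, 560, 45), simplify = FALSE))
  est <- permutation_reliability(tr, "it", n_permutations = 5000, seed = 18)
  set.seed(19)
  naive <- replicate(2000, naive_split_half(tr, "it_ms"))
  se <- sqrt(sd(attr(est, "r_sb"), na.rm = TRUE)^2 / 5000 +
               sd(naive, na.rm = TRUE)^2 / 2000)
  expect_lt(abs(est$mean_r_sb - mean(naive, na.rm = TRUE)), 3 * se)
})

test_that("component score types correlate single-condition half means", {
  set.seed(33)
  base <- rnorm(20, 500, 60)
  tr <- make_cell_trials(lapply(base, function(b) rnorm(6, b, 20)),
                         lapply(base, function(b) rnorm(6, b + 50, 20)))
  estC <- permutation_reliability(tr, "it", "congruent_component",
                                  n_permutations = 300, seed = 4)
  estI <- permutation_reliability(tr, "it", "incongruent_component",
                                  n_permutations = 300, seed = 4)
  expect_gt(estC$mean_r_sb, 0.9) # baseline variance dominates trial noise
  expect_gt(estI$mean_r_sb, 0.9)
})

test_that("component reliabilities exceed difference-score reliability on shared-baseline data", {
  cfg <- sim_config(n_participants = 50, n_blocks = 2, trials_per_block = 48,
                    seed = 55)
  ret <- filter_trials(code_conditions(simulate_dataset(cfg)))$retained
  rep_tab <- reliability_report(ret, measures = "it",
                                n_permutations = 300, seed = 5)
  diff_est <- rep_tab$mean_r_sb[rep_tab$score_type == "difference"]
  comp_est <- rep_tab$mean_r_sb[grepl("component", rep_tab$score_type)]
  expect_true(all(comp_est > diff_est))
})

test_that("more trials never hurt expected reliability (monotone refinement)", {
  means <- sapply(c(16, 64), function(tpb) {
    vals <- sapply(1:4, function(s) {
      cfg <- recovery_sim_config(tau = 30, sigma = 60, trials_per_block = tpb,
                                 n_participants = 60, seed = 100 + s)
      tr <- simulate_dataset(cfg)
      permutation_reliability(tr, "it", n_permutations = 200,
                              seed = 200 + s)$mean_r_sb
    })
    mean(vals)
  })
  expect_gt(means[2], means[1])
})
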