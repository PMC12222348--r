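---
title: "Measuring and estimating the reliability of reaching congruency effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and estimating the reliability of reaching congruency effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachcong)
```

## The problem

Congruency tasks (flanker, Stroop, Simon) index conflict processing through a
difference score: mean performance on incongruent trials minus mean
performance on congruent trials. Difference scores computed from button-press
response times are notoriously unreliable for individual-differences work,
because subtracting two highly correlated component scores removes most of
the true between-participant variance while keeping all of the trial noise.
Reaching and release-and-press task variants decompose the response time (RT)
into an initiation time (IT, stimulus onset to movement onset) and a movement
time (MT, movement onset to response completion), and — when trajectories are
recorded — a reach curvature (CURV, the maximum deviation of the observed
path from the direct start-to-target path divided by the direct path length).
These component measures isolate dissociable processes and can each carry
their own, often higher, reliability.

`reachcong` implements the full measurement-and-reliability pipeline for such
tasks: measure extraction from raw trajectories, trial-sequence coding, a
standard exclusion ladder, congruency-effect difference scores, permutation
split-half reliability with Spearman–Brown correction, the analytic
difference-score reliability identity, and 2×2×2 within-subject sequence
ANOVAs — together with a synthetic data generator whose true reliability is
known in closed form, so that every estimator in the package can be validated
against ground truth without any data download.

## The generative model

`sim_config()` parameterises a dual-process random-effects model. For
participant $i$ on trial $t$:

$$\mathrm{IT}_{it} = \beta^{IT}_i + a_i\,[n=\mathrm{I}] +
  b_i\,[n{-}1=\mathrm{i}] + \varepsilon_{it}, \qquad
  \varepsilon_{it} \sim N(0, \sigma_{IT}^2)$$

$$\mathrm{MT}_{it} = \beta^{MT}_i + c_i\,[n=\mathrm{I}] +
  g_i\,[\mathrm{cI\text{-}r}] + \kappa\, f_{it}\,[\text{partial error}] +
  \eta_{it}, \qquad \eta_{it} \sim N(0, \sigma_{MT}^2)$$

with $\mathrm{RT} = \mathrm{IT} + \mathrm{MT}$. The indicator
$[\mathrm{cI\text{-}r}]$ marks incongruent trials that follow a congruent
trial and repeat the previous response — the cell in which MT slowing
concentrates, producing the characteristic three-way interaction while IT
carries main effects of both current and previous congruency. All
coefficients ($\beta_i, a_i, b_i, c_i, g_i$) are drawn per participant from
normal distributions; trial times are truncated below at 1 ms by resampling.
Congruency is balanced and randomised within block; target side is random,
so response repetitions arise at ~50% without explicit scheduling. Partial
errors occur independently per trial with condition-specific probabilities
and add a correction cost $\kappa f_{it}$ proportional to the commitment
fraction $f_{it}$ (how far the reach initially heads toward the wrong
target); overt errors flip the response side.

### Default calibration

Defaults describe a keyboard release-and-press flanker study with 51 adults
and 4 blocks of 48 trials. The current-congruency effect means/SDs (IT 30/36
ms, MT 56/28 ms) follow the published keyboard-condition congruency-effect
descriptives. Values the literature does not report are package conventions,
chosen once for realism and documented here:

* trial-noise SDs: IT 60 ms, MT 65 ms — consistent, through the
  variance-components identity below, with split-half reliabilities near
  0.94 (IT) and 0.88 (MT) at ~80 retained trials per cell;
* previous-congruency effect on IT 12/20 ms and cI-r slowing 40/20 ms —
  magnitudes consistent with the reported F statistics of the corresponding
  sequence effects at $N = 51$;
* baselines IT 350 ± 50 ms, MT 300 ± 50 ms between participants; shared
  baselines are what drive the very high component-score correlations and
  component reliabilities seen in adult data;
* partial-error probabilities 0.15 (incongruent) / 0.03 (congruent),
  overt-error probabilities 0.02 / 0.004 (error rates near 1%, concentrated
  on incongruent trials), correction cost $\kappa = 100$ ms at full
  commitment;
* geometry: start (0, 0) mm, targets (±100, 280) mm, loosely mirroring a
  touchscreen layout; sampling rate 100 Hz (trackers vary; configurable).

Because the effect coefficients have known between-participant variance
$\tau^2$ and the noise known variance $\sigma^2$, the full-length reliability
of a congruency-effect difference score based on $n_C$ and $n_I$ retained
trials is

$$\rho = \frac{\tau^2}{\tau^2 + \sigma^2 (1/n_C + 1/n_I)},$$

returned by `true_reliability()` / `reliability_from_components()`. For MT
the cI-r coefficient loads on a quarter of incongruent trials, contributing
$\tau^2_{g}/16$; RT adds the IT and MT components. The partial-error
correction cost is ignored in the closed form — at default rates it shifts
the MT effect by under 4 ms and its variance contribution is negligible; the
recovery tests therefore use configurations with partial errors disabled so
the closed form is exact.

```{r}
reliability_from_components(36^2, 60^2, 80, 80)
```

### What the generator does not emulate

Real reach data have autocorrelated drifts (fatigue, practice), non-normal
RT distributions with heavy right tails, speed–accuracy trade-offs coupling
error rates to times, and age-graded noise. The generator reproduces none of
these: passing tests show the estimators are correct under the stated model,
not that any particular real dataset satisfies it. The log-transform path
exists precisely because real effect distributions are skewed even though the
generator's are not.

## Trajectory synthesis and measure extraction

In trajectory mode every trial gets time-stamped positions: at the start
point (plus Gaussian jitter) before onset, then along the direct path to the
responded target — or, on partial-error trials, toward the wrong target for
the commitment fraction of the movement and then smoothstep-redirected. The
sample clock re-synchronises at movement onset so that the first post-onset
sample falls exactly one period into the movement; with the default 5 mm
displacement threshold this keeps extracted IT within one sample period of
the generating IT (the reason is practical: with a free-running clock the
threshold crossing can lag by a period *plus* the time to cover 5 mm).
The final sample is pinned to the target, making the end point and the
response completion time exact.

Onset detection uses a displacement threshold (default 5 mm), not velocity —
velocity criteria need differentiation and filtering choices that raw
low-rate data cannot always support. Curvature measures the perpendicular
distance to the *infinite line* through the onset position and end point,
matching the ratio definition above; segment-based variants give slightly
different values on hooked paths, which is worth knowing when comparing
implementations.

## The exclusion ladder

`filter_trials()` applies, in order: first-of-block trials; overt errors;
post-error trials; absolute RT bounds (< 200 ms, or > 2.5 s for adults and
> 4 s for children); and a per-participant 3-SD rule on RT, with mean and SD
computed per congruency condition (within interface condition) on the
survivors of the earlier stages. Each trial is attributed to the first rule
that catches it, so the per-rule exclusion log is additive. Decisions where
the conventions were genuinely open:

* "condition" for the SD rule means the congruency level within interface
  condition; not stratified by previous congruency.
* The SD rule tests RT only and removes the whole trial from all measures.
* "Post-error" refers to overt errors only; an excluded-but-correct trial
  does not re-trigger the rule.
* Error-rate effects are computed from bounds-filtered but
  accuracy-unfiltered trials (`exclude_errors = FALSE`,
  `exclude_post_error = FALSE`, `apply_sd_rule = FALSE`).
* The log transform is the natural log; on log-ms data congruency effects
  become differences of log-means (ratios), typically 0.05–0.3.

A known limitation: the single-pass 3-SD rule is not exactly idempotent.
Removing an outlier shrinks the recomputed SD, so re-filtering retained
output can occasionally catch one more trial (about 0.1% of trials in
simulation). An iterative rule would be idempotent but would not match the
single-pass convention standard in this literature; we keep the single pass.

## Permutation split-half reliability

For each random split, trials are partitioned within each participant ×
congruency cell into halves of size $\lfloor n/2\rfloor$ and
$\lceil n/2\rceil$ (membership random, so the odd trial lands in either half
exchangeably); half-wise scores are computed (difference score, or one
condition's mean for component scores); the half-1 and half-2 scores are
correlated across participants (Pearson); and the Spearman–Brown correction
$2r/(1+r)$ is applied. `permutation_reliability()` repeats this (default
5000 splits), reports the mean of the corrected correlations, and takes the
2.5th/97.5th percentiles of the permutation distribution as the 95%
interval. Implementation choices:

* **Correct-then-average.** Each split's $r$ is Spearman–Brown-corrected
  before averaging. Averaging first and correcting once gives slightly
  different values because the correction is concave; correcting per split
  matches the common permutation-splithalf practice.
* **Percentile interval.** The bracketed interval summarises the split
  distribution. It is not a sampling CI over participants; with no true
  individual differences it still covers zero in the large majority of
  datasets, which is what the null-recovery tests check.
* **Stratification by congruency only**, keeping C/I balanced within halves;
  no finer stratification by sequence condition.
* **Minimum 2 trials** per required cell; participants below are dropped for
  that measure and counted in the output.
* Splits with zero variance in a half (or $r = -1$) are invalid: counted,
  excluded from aggregation, and flagged when they exceed 10%.

The engine is vectorised (one `order()` and one `rowsum()` per split over
the pooled trial vector), so 5000 splits on 100 participants with 160 trials
each take a few seconds. Its correctness is checked two independent ways:
exact enumeration of the complete joint split space on a fixture small
enough to enumerate (6 participants × 2 trials per cell: $2^{12}$ splits),
and agreement with a naive loop-based reimplementation on a 12 × 4 fixture.
Qualitative labels use the conventional cutoffs (poor < 0.70 ≤ acceptable
< 0.80 ≤ good < 0.90 ≤ excellent) applied after rounding to two decimals;
exactly 0.90 is labelled excellent, following the common table convention
for the 0.90–1.0 band.

The analytic identity
`difference_score_reliability_analytic()` connects component reliabilities,
their correlation, and their SDs to the difference-score reliability; on
simulated data the identity evaluated at *estimated* components agrees with
the direct permutation estimate to within 0.05, a useful internal
consistency check on real datasets too.

## Sequence-effect ANOVAs

`cell_means()` builds unweighted per-participant means for the eight cells
of trial-$n$ congruency × trial-$n{-}1$ congruency × response repetition
(first-of-block trials excluded; participants with an empty cell excluded
listwise — no imputation). `rm_anova_2x2x2()` forms each of the seven
effects as a ±1-weighted contrast over the eight cell means, and computes
$F(1, N{-}1) = N \bar{c}^2 / s_c^2$ — the squared paired $t$, exact for
two-level within factors. The implementation is cross-validated in the test
suite against `stats::aov()` with `Error()` strata. Unweighted (not
trial-weighted) cell means are a convention, stated here because sequence
cells are mildly unbalanced by design. Type-I error of all seven effects is
calibrated at 5% on null-model data over 200 simulated datasets.

## Problem sizes and numerical choices

Test and validation runs use: recovery at 100 participants with ~80 retained
trials per cell over 10 seeds (tolerance ±0.05 around the closed form, which
at $\tau = 36$, $\sigma = 60$ ms gives 0.935); null coverage over 10 seeds;
pattern reproduction at the default $N = 51$ over 10 seeds; and type-I
calibration over 200 null datasets at $N = 20$. These sizes make the whole
validation suite run in a few minutes while keeping Monte-Carlo error well
inside the asserted tolerances. Ties in onset detection cannot occur
(strictly increasing timestamps); quantiles use R's default type 7;
reliability aggregation ignores invalid splits rather than imputing them.

## Worked example

```{r, eval = FALSE}
cfg <- sim_config(seed = 1) # keyboard-like study, N = 51
res <- run_pipeline(cfg, n_permutations = 5000, reliability_seed = 2)
res$reliability[, c("measure", "mean_r_sb", "ci_low", "ci_high", "label")]
res$anova[res$anova$effect == "n_x_prev_x_rep", ]
```

On this configuration the RT, IT, and MT congruency effects come out with
split-half reliabilities near 0.9 ("good" to "excellent"), the IT ANOVA
shows main effects of current and previous congruency, and the MT ANOVA a
large three-way interaction driven by the cI-repetition cell — the pattern
the generator encodes and that motivates separating IT from MT in the first
place.

## Limitations

* The generator's normality and independence assumptions are conveniences;
  estimator behaviour under heavy-tailed or drifting data must be checked
  against real datasets.
* CURV reliability depends on partial-error rates, which the generator
  exposes but does not calibrate to any population.
* No test–retest reliability, Cronbach's alpha, ICC, or hierarchical
  reliability models; the scope is the permutation split-half machinery and
  its analytic companions.
* Release-and-press datasets carry no trajectories, so CURV is absent there
  by construction.
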