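---
title: "Norm ranges, intended consumption, and categorical discrimination: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Norm ranges, intended consumption, and categorical discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normrange)
library(dplyr)
```

This vignette documents the statistical models behind `normrange`, the
generative model its synthetic cohorts follow, and the design decisions
taken wherever the underlying analysis strategy leaves room. It states no
empirical result beyond what the package's own test suite and
`scripts/acceptance.R` compute.

## 1. The norm-range estimator

All stimuli are portion sizes in integer percent of a reference serving,
on an arithmetic grid (typically 40–300% in 10% steps, 27 sizes). A
**collective norm range** for a food is defined by a clear-majority rule:
a size qualifies when at least `ceil(τ·N)` participants judge it normal,
with τ = 0.60 by default (36 of 60). The lower boundary is the smallest
qualifying size and the upper boundary the largest. An **individual norm
range** applies the same τ to a participant's repeated judgments: a size
qualifies when judged normal on ≥ 60% of its repetitions (6 of 10).

Decisions worth making explicit:

* **Ties qualify.** "≥ 60%" is read inclusively, so exactly 36/60 votes or
  6/10 repetitions qualify. The comparison is guarded against binary
  floating-point artefacts (`0.7 * 10 > 7` in doubles).
* **Non-contiguous majority regions.** The rule defines only the smallest
  and largest qualifying sizes, so an interior size that dips below the
  criterion does not shrink the range; the estimator warns and keeps the
  min/max span. This case is rare at realistic noise levels but must be
  well-defined.
* **Boundaries are inclusive.** A portion equal to a boundary size counts
  as *within* the range; printed spans such as 80–160% are read
  inclusively.
* **Repeated judgments feed the collective rule through binary verdicts.**
  With repetitions available, each participant is first reduced to a
  per-size verdict by the same τ, and the participant-majority rule is
  applied to the verdicts. This keeps the single-judgment and
  repeated-judgment collective paths structurally identical.
* **Invalid ranges drop per food, not globally.** A participant with no
  qualifying size for one food is excluded from that food's analyses only,
  and every exclusion is counted in the run log.
* Raising τ can only shrink a range (monotonicity) — enforced by a
  property test.

We deliberately do not fit smooth psychometric functions to the normality
data; the threshold rule *is* the estimator under study.

## 2. Portion and pair categories

A valid range partitions the grid into **below / within / above**. Pairs of
sizes a fixed Δ = 20 percentage points apart are classified as
`across_lower`, `within`, `across_upper` — the three analysed positions —
plus `outside_below`, `outside_above` and `spanning` for completeness.
Pairs entirely outside the range, or spanning a very narrow range, are
excluded from the three-category analyses (the conservative reading, since
the analysis defines only three positions); exclusion counts are reported.

## 3. Inferential machinery

* **One-sample and paired t-tests** delegate to `stats::t.test()`, wrapped
  so zero-variance cells return flagged degenerate results (t = 0, p = 1
  at the null value; ±Inf, p = 0 otherwise) instead of raising — essential
  for large simulation sweeps.
* **Repeated-measures ANOVA** is a fully within-subjects one- or two-way
  decomposition on one observation per subject × cell. Each effect is
  tested against its own subject-interaction error term; effect size is
  partial η² = SS_effect/(SS_effect + SS_error). Sphericity is handled by
  the Greenhouse–Geisser ε estimated from the orthonormalised contrast
  covariance (exactly 1 for two-level factors), applied to both dfs. GG is
  the conventional default; the correction is switchable because the
  original analysis strategy does not pin down the method. The engine is
  cross-validated against `car::Anova()` (univariate repeated-measures
  path) and `stats::aov()` error strata to 1e-6 in the test suite.
* **Multiplicity** uses Bonferroni thresholds α/κ with κ per family
  supplied by configuration (15 midpoint tests for five foods × three
  categories in a five-food design; 6 in a two-food design), displayed in
  the conventional three-decimal style (".003", ".008").
* **Follow-up policy**: a significant category × food interaction triggers
  per-food one-way repeated-measures ANOVAs, then adjacent-category paired
  comparisons at the configured corrected level.

## 4. The synthetic cohort generator

The generator is first-class, tested code: it encodes the hypothesised
generative structure so each analysis stage can be validated by parameter
recovery.

**Boundaries.** Each participant draws true boundaries L ~ N(μ_L, σ_L),
U ~ N(μ_U, σ_U), redrawn until L < U. Defaults μ_L = 85, σ_L = 12,
μ_U = 160, σ_U = 18 put collective ranges in the neighbourhood of the
published 70–190% spans across foods. Judgment noise is a soft category:
P(normal at s) = Λ((s−L)/k_L)·Λ((U−s)/k_U) with Λ the standard logistic
and k = 5 by default; k = 0 is the exact indicator, used for noiseless
recovery tests.

**Intention.** The latent intention is piecewise linear and continuous,
anchored at the Likert midpoint at the range centre c = (L+U)/2:
4 + β_within·(c−s)/100 inside, continuing with slope β_below below L and
β_above above U (all in Likert units per 100 percentage points). Observed
ratings add N(0, σ_int) noise, round to the nearest scale point and clamp
to 1–7. Defaults β_below = β_above = 4, β_within = 1, σ_int = 0.6: the
steep outer slopes against a shallow inner slope are the minimal
parameterisation that produces both the category ordering (below > within
> above with within ≈ 4) and, when β_below > β_within = β_above,
asymmetric boundary sensitivity. The ordinal predictions constrain only
the signs and ordering of the slopes; the numeric defaults are our choice
of a clearly detectable but not saturated effect at n = 40.

**Discrimination.** Pair discriminability is d = Δ/(w·s̄) + b·1[crossing]:
Weber's law with fraction w = 0.15 plus a categorical boost b whenever the
two members fall in *different* categories of the participant's true range
(this includes pairs spanning a very narrow range — any category change
boosts discriminability). Accuracy is Λ(a·d) with scale a = 1.5, giving
chance 0.5 at d = 0, ≈ 0.88 for a 20-point pair at s̄ = 100 and ≈ 0.67 at
s̄ = 290 — discrimination that visibly worsens along the grid. RT is
shifted-lognormal, t0 + exp(μ_RT − γ·d + N(0, σ_RT)) with t0 = 300 ms,
μ_RT = 8.2, γ = 0.25, σ_RT = 0.4, so RTs of a few seconds that shorten
with discriminability. Contamination exists purely to exercise the
trimming stage: with probability 0.01 a trial becomes anticipatory
(Uniform(100, 349) ms) and with probability 0.01 a lapse (RT × 10), giving
roughly 2% total loss under the default trim.

**Counterbalancing and determinism.** The larger portion's screen side
alternates across repetitions within pair; the judgment instruction
(larger/smaller) alternates by participant index. Every stage seeds its
own deterministic sub-seed derived from the single config seed, so a
config is byte-reproducible regardless of which stages are run.

The generator deliberately omits features of real data: no hunger, BMI,
gender or appetite covariates, no sequential effects, no learning or
fatigue, no food-specific response styles, and boundary, intention and
discrimination parameters are independent across participants. Passing
recovery tests therefore show the *pipeline* is correct under the stated
model, not that the model exhausts real behaviour.

## 5. RT trimming and the discrimination pipeline

Trials faster than 350 ms are removed first (anticipations); the outlier
bound mean + 3 SD is then computed on the RTs that survive the floor,
pooled across the whole sample, and slower trials are removed. Pooling
matches an analysis that reports a single sample-level threshold;
per-participant bounds are available as an option. Computing the SD after
floor removal is the stabler reading (anticipations would otherwise
inflate the SD) and is the package default. Trimming drops whole trials,
so accuracy as well as RT is computed on retained trials. A brute-force
filter reproduces the retained set exactly in a 100-fixture property test,
and bookkeeping (input = retained + floor-removed + outlier-removed) is
asserted throughout.

The boundary analysis averages per-pair accuracy and correct-trial RT to
participant × food × boundary-category cells and applies the same ANOVA
machinery, with an optional natural-log RT rerun as a skewness sensitivity
check.

## 6. The Weber/categorical decomposition

The question "is discrimination boundary-locked beyond Weber's law?" is
answered by a per-participant logistic regression of trial-level
correctness on the Weber predictor Δ/s̄ and an indicator that the pair
crosses a boundary of that participant's **estimated** individual range
(using the analysis-time object keeps the decomposition honest about
estimation error; swapping in generator truth is available as a
diagnostic). Coefficients are summarised across participants by mean, SE
and one-sample t — a summary-statistics approach chosen over a mixed
model for transparency and robustness at 40 participants. Participants
with non-convergent or separated fits (coefficient SE above a cap, default
50) or without both crossing and non-crossing pairs are flagged and
excluded, with counts reported. A parallel linear model of log RT on the
same predictors runs on correct trials. Recovery at the design size
(40 participants × 10 repetitions): the crossing coefficient is null when
the generator's boost is zero, and detected with power above 0.9 at boost
0.8.

## 7. Difference-score orientation and other open calls

* Pair difference scores are **signed**, rating(small) − rating(large), so
  expected values are positive when intention falls with size; absolute
  values would bias null comparisons upward.
* Category means average over sizes (each size contributes one rating, as
  collected), not over trials.
* The two Bonferroni families (midpoint tests; follow-up pairwise
  comparisons) are configuration, not hard-coded, because family
  definitions belong to the analysis plan rather than the machinery.

## 8. Problem sizes used by the automated checks

The test suite and acceptance script run at the study design size of 40
participants throughout: 200 simulated cohorts for the category-means
signature, 500 for the boundary-sensitivity asymmetry and its type-I
calibration, 30 for decomposition power (the acceptance script uses
100/200/30 to keep a single run brief), 100 random fixtures for the
trimming oracle, and 2000 replicates for the t-test calibration check.
These sizes give Monte-Carlo standard errors comfortably below the margins
being asserted.

## 9. Known limitations

* The ANOVA engine handles one or two within-subject factors with complete
  data only — exactly the designs used here; unbalanced or mixed designs
  are out of scope.
* The decomposition's per-participant GLMs can be fragile when a
  participant has very few boundary-crossing pairs (a narrow or extreme
  estimated range); such participants are excluded and counted rather
  than stabilised by shrinkage.
* Collective-range analyses classify every participant by the same
  boundaries; participants whose own boundaries sit far from the
  collective ones add heterogeneity that individual ranges remove. Both
  paths are provided.
* Likert rounding means simulated mean differences match their
  closed-form latent values only up to discretisation; exact algebraic
  checks in the tests therefore operate on the latent scale.
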