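---
title: "Methods: from smartphone event streams to pooled severity models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from smartphone event streams to pooled severity models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phenoframe implements a complete digital-phenotyping analysis pipeline for
depression severity: raw smartphone event streams and ecological momentary
assessments (EMA) are turned into day-level behavioral features, assembled
into 14-day episodes anchored to PHQ-8 questionnaires, multiply imputed at
the day level with a two-level chained-equations model, aggregated to
episode-level means and SDs, and analyzed with Rubin's-rule-pooled
correlations and confidence-interval-driven stepwise regressions. Because
raw sensing cohorts of this kind are essentially never shareable, the
package also ships a synthetic-cohort generator with known ground truth, so
every stage can be validated by parameter recovery rather than by
comparison to irreproducible empirical coefficients.

This vignette documents the modeling choices, the tunable parameters and
their defaults, the numerical decisions, and what the synthetic validation
does and does not establish about real data.

## The data model

Five delimited-text streams describe one cohort (see `write_cohort()` for
the schemas): screen lock/unlock events, app foreground episodes, call
records (direction, hashed contact, duration), GPS fixes, and EMA
responses (eight items on 0-100 sliders, up to three prompts per day), plus
a PHQ-8 log (eight items scored 0-3, summing to 0-24; sums of 10 or more
conventionally flag clinically relevant severity). All timestamps live in
one fixed timezone and a day is the local interval [00:00, 24:00); the
pipeline deliberately does not model timezone changes or daylight-saving
shifts.

## Day-level features

`extract_day_features()` computes the feature set listed in
`feature_dictionary()`. Durations are reported in hours, distances in km,
entropies in nats. The less obvious concretizations:

* **Screen sessionization.** Unlock events open an episode and the next
  lock closes it. Event streams from real devices are imperfect, so the
  pairing policy is conservative: a second unlock closes the open episode
  at the second unlock (zero-gap policy), an orphan lock is dropped, and
  an episode still open at the end of the stream is dropped. Episodes are
  clipped at local midnight so per-day durations are conserved exactly.
* **Screen entropy** is the Shannon entropy of the day's on/off duration
  shares (time unlocked vs. locked over 24 h). A count-based reading would
  be degenerate -- unlock and lock episodes alternate, so their counts are
  always nearly equal -- whereas duration shares vary meaningfully across
  days and participants.
* **Entropy base.** Natural log everywhere. Normalized entropy (entropy
  over log of the number of states) is base-invariant, so the choice only
  affects the unnormalized features, uniformly.
* **Regularity indices** (screen, app, location routine) share one
  definition: build a days-by-24 matrix of the dominant state per hour
  (most frequent screen state; longest-running app, or "none"; dominant
  significant cluster, or "away"), then average over all unordered day
  pairs the fraction of the 24 hours on which the two days agree. The
  index is 1 for a perfectly repeated daily schedule and is undefined
  (missing) with fewer than two days. Regularity-type features are
  computed once per observation window -- with the 14-day episode as the
  intended window -- because hour-by-hour similarity across days has no
  single-day analogue; they are repeated on each day row and are constant
  within an episode.
* **Motion classification** uses the speed between consecutive fixes
  (haversine distance over elapsed time, Earth radius 6371 km) with a
  1 km/h threshold; exactly 1 km/h counts as static (the tie goes to the
  static side so that jitter around a stay point never fabricates
  movement). Duplicate timestamps keep the first fix.
* **Significant places.** Pauses (maximal runs of at least two static
  fixes, split at recording gaps longer than 1 h) are clustered by k-means
  with k grown from 1 while all centroids stay at least 400 m apart;
  pauses within 200 m of a centroid are visits, others outliers; clusters
  with at least 10 minutes of total dwell are significant. Location
  entropy is computed over significant-cluster dwell shares, the
  normalized form divides by log of the number of significant clusters
  (defined only with two or more), transitions count changes of assigned
  cluster between consecutive pauses, and outlier time is expressed
  relative to total significant dwell. k-means restarts use an internal
  fixed seed so feature extraction is deterministic and leaves the
  caller's RNG untouched.
* **Circadian movement** is the log of the Lomb-Scargle spectral power of
  the latitude and longitude series, averaged over 24 frequencies spanning
  periods of 23.5-24.5 h and summed over the two axes. A constant axis
  contributes zero power; the feature is missing when the trace spans
  fewer than two days or has no spatial variance at all.
* **Missingness semantics.** A day with no events for a sensor yields
  missing values for that sensor's duration/entropy features and zero for
  its counts (no calls is an observation of zero calls; an unobserved call
  duration is not an observation of zero hours). Days with no events in
  any stream produce no row at all and enter episodes as fully missing.

## Episodes and eligibility

A PHQ-8 asks about the preceding two weeks, so `build_episodes()` anchors
each episode at the questionnaire date and takes that day plus the 13
preceding days. Partially answered questionnaires are dropped. Episode
missingness is the fraction of missing cells over 14 days times the
counted feature columns, EMA and sensing pooled with equal weight. Per
participant, the episode with the lowest missingness is kept (earliest
date on ties), and participants whose best episode exceeds 50% missing
cells are excluded -- strictly, so exactly 0.5 is retained.

## Two-level multiple imputation

Imputation runs at the day level, where the missingness actually occurs,
and only then aggregates to episode-level means and SDs; imputing the
aggregates directly would discard the within-person structure.
`impute_pmm()` implements chained equations with predictive mean matching
under a participant-level random intercept:

1. For each incomplete variable (visited in order of ascending
   missingness), regress it on all other feature columns plus the
   episode-constant PHQ-8 sum, using the observed rows.
2. The fixed part is ordinary least squares; the variance components come
   from a between/within decomposition of the residuals, and each
   participant's predicted intercept is the participant's mean residual
   shrunken by the intraclass-correlation factor
   sigma_b^2 / (sigma_b^2 + sigma_e^2 / n_i). Participants with no
   observed rows get intercept zero. This moment estimator keeps the
   sweep fast and dependency-light while preserving the two-level
   structure; a full REML fit per variable per cycle would change little
   besides runtime, since predictions feed a matching step rather than
   being used as imputed values themselves.
3. Fixed effects are perturbed by a draw from their estimated sampling
   distribution, predictions are formed for all rows, and each missing
   row copies the observed value of one of the `donors` (default 5)
   nearest-prediction rows, drawn uniformly.

Defaults are m = 20 completed datasets and 10 cycles; the validation
suites scale these down (m = 5, 5 cycles) to keep replication studies
fast, which parameter-recovery results show is already sufficient for
stable pooling at the cohort sizes used. PMM guarantees imputed values
stay on the observed support; observed cells are never altered; collinear
or constant predictors are pruned per equation (rank-revealing QR plus a
zero-variance filter). `convergence_report()` compares the last-three-
cycle trend of imputed-value means against the between-chain spread.

## Pooled inference

All estimates are pooled across the m completed datasets by Rubin's
rules: total variance T = W + (1 + 1/m) B, with the Barnard-Rubin
small-sample degrees of freedom combining (m - 1)/lambda^2 with the
observed-data df. With no missing data every chain returns the same
table, B = 0, and each pooled quantity equals its single-dataset
counterpart exactly -- a property the test suite asserts.

* **Correlations** are pooled on the Fisher z scale (variance
  1/(n - 3)); pooling r untransformed would violate the variance
  assumptions of Rubin's rules near |r| = 1. The CI is back-transformed.
* **Screening**: features whose pooled 95% CI excludes zero (evaluated
  on unrounded bounds) become regression candidates, grouped into the
  EMA, app, call, location, and screen clusters.
* **Regression**: outcome and predictors are z-scored per dataset, OLS
  coefficients are pooled per predictor (complete-data df = n - p - 1),
  and adjusted R^2 = 1 - (1 - R^2)(n - 1)/(n - p - 1) is pooled on the
  Fisher-z-of-sqrt scale and reported in percent. AIC/BIC are averaged
  arithmetically and used only for model ordering. Negative per-dataset
  adjusted R^2 is floored at zero before the transform, so the pooled
  value and CI live in [0, 100).
* **Stepwise backward elimination** removes, among predictors with
  zero-including CIs, the smallest-|beta| one (ties: wider CI, then
  name -- fully deterministic), refitting after each removal. Once every
  CI excludes zero, removal continues only while it still increases
  adjusted R^2 (with standard OLS fits this extra phase almost never
  fires, because a CI excluding zero implies |t| > 2 and removal then
  lowers adjusted R^2). An empty final model is a legal outcome. The
  full elimination trace is retained.
* **Model suite**: stand-alone models per cluster; a sensing-combined
  model whose candidate pool is the union of the sensing clusters' final
  predictors (the union of all screened sensing candidates is available
  via `sensing_pool = "screened"`); a combined EMA + sensing model; and
  age/gender sensitivity refits. Adjusted-R^2 differences quantify the
  incremental value of combining modalities.

## The synthetic cohort generator

`generate_cohort()` draws a latent severity per participant from a gamma
distribution matched to a right-skewed subclinical profile (mean 5.8,
SD 4.4 on the 0-24 scale) and truncated to [0, 24]; truncation pulls the
realized SD slightly below the target (about 4.2), which is accepted
rather than corrected since the profile is a default, not an estimand.
PHQ-8 items are independent Binomial(3, severity/24) draws, so the item
sum is unbiased for the latent severity with the zero-noise limits exact.

Correlations are injected *between persons*, matching the analysis: for a
feature with target correlation r, the participant-level generating
parameter loads on standardized severity with coefficient
r / (lambda_f lambda_p), where lambda_f is the attenuation from day-level
noise averaged over the 14-day window and lambda_p the attenuation from
PHQ-8 discretization (both computed from the configured population
moments). The target is therefore what the downstream pipeline should
recover; targets whose required loading exceeds 0.95 are rejected as
infeasible. The renderer then emits event streams whose extracted daily
values equal the generated ones exactly (equal-duration screen episodes
placed in non-overlapping slots, and so on), so injection survives
feature extraction. Only features the renderer can realize exactly are
injectable (`injectable_features()`); the effect map alone controls
loadings -- an empty map yields an all-null cohort, and
`default_effect_map()` provides a study-patterned profile.

GPS traces move among three per-participant anchor points (home, work,
other; pairwise at least 550 m apart) on a fixed daily schedule with
linear transits and Gaussian jitter of 25 m, giving place clustering a
known ground truth of three significant clusters per day. Missingness
drops whole sensor-days with configurable probability -- optionally
mechanism-not-at-random via a logistic severity term (default slope 0,
i.e. MCAR) -- and EMA prompts independently.

`simulate_day_table()` is the generator's statistical twin: identical
latent structure and daily values, no event rendering. Replication
studies (imputation coverage, stepwise recovery) use it because rendering
and re-extracting thousands of event streams adds cost but no
information about the statistical machinery under test.

What the synthetic validation does **not** show: real behavioral streams
have autocorrelated days, weekday/weekend structure, drifting schedules,
device-specific logging artifacts, and missingness tied to behavior
itself. Recovery on this generator validates the pipeline's statistical
correctness, not the empirical effect sizes of any particular cohort.

## Validation design and problem sizes

The test suite validates each primitive against an independent oracle
(brute-force entropy sums, pairwise agreement counts, an independent
haversine implementation, hand-derived Rubin formulas, `summary.lm`'s
adjusted R^2) on hundreds of random instances, then checks the pipeline
end to end by parameter recovery, at sizes chosen to keep the full suite
in the minutes range:

* complete-data recovery of injected correlations from raw events at
  n = 500 participants (tolerance two Monte-Carlo SEs);
* 95% CI coverage of an injected correlation of at least 85% over 50
  replicates at n = 150 with 20% MCAR cells and the scaled-down
  imputation (m = 5, 5 cycles);
* exact recovery of an injected two-predictor EMA model among eight
  candidates (targets patterned on a valence-like -0.55 and a social-
  quality-like -0.51 effect) in at least 80% of 25 replicates at
  n = 200 -- the screening stage matters here: feeding all eight
  features to stepwise without screening lets roughly one in four runs
  retain a spurious predictor, while screening plus stepwise keeps the
  exact pair close to nine times in ten;
* ground-truth anchor-count recovery on 20 GPS traces (anchors >= 550 m
  apart, 25 m jitter), with the 10-minute dwell rule filtering
  sub-threshold visits.

## Study planning

`smd_to_r()` converts a standardized mean difference to the equivalent
correlation, d / sqrt(d^2 + 4). `required_n_correlation()` finds the
smallest n at which a two-sided Fisher-z test of zero correlation reaches
the requested power, including the small-sample bias term r/(2(n - 1)) in
the transformed effect; without that term the minimum for r = 0.12 at 80%
power and alpha = 0.05 lands one participant higher (543 instead of 542).
The implementation is checked against a brute-force power scan over n
with both rejection tails, and agreement is required to plus/minus one
participant.

## Known limitations

* The regularity/circadian window is the participant's full observed
  span; when participants contribute more days than one episode, the
  window-level features blend behavior outside the selected episode.
* The moment-based variance components can hit the sigma_b^2 = 0 boundary
  in small cohorts, collapsing to single-level PMM for that variable and
  cycle.
* The imputation model is linear in the other features; strongly
  nonlinear feature relationships are only captured through PMM's
  donor matching.
* The generator's day-to-day noise is i.i.d. within person; it does not
  emulate autocorrelation or weekly rhythm.
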