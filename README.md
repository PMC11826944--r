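# phenoframe

Smartphone digital-phenotyping pipeline for depression severity.

Passively sensed smartphone data — screen lock/unlock events, app
foreground episodes, call records, GPS fixes — together with brief
in-situ self-reports (ecological momentary assessment, EMA) can track
behavioral correlates of depression between clinic visits. phenoframe
implements the full analysis chain such studies need, for
methodologists and study teams who want a tested, reproducible
reference implementation:

1. **Features** — per-day behavioral features from raw event streams:
   screen episode counts/durations/entropy/regularity, app usage and
   frequency entropy, per-direction call aggregates, and GPS-derived
   mobility (total haversine distance, log location variance,
   moving/static ratio, significant-place clustering with a 400 m
   centroid separation, 200 m visit radius, and 10-minute dwell
   significance rule, location entropy, circadian movement, routine
   index), plus daily EMA means.
2. **Episodes** — 14-day blocks anchored at each PHQ-8 questionnaire
   (its recall window), with cell-level missingness accounting,
   best-episode selection per participant, and the >50%-missingness
   exclusion rule.
3. **Imputation** — two-level (participant random intercept)
   predictive mean matching by chained equations at the day level
   (default m = 20 completed datasets, 10 cycles), then aggregation to
   episode-level 14-day means and SDs.
4. **Inference** — Pearson correlations with PHQ-8 severity pooled by
   Rubin's rules on the Fisher z scale with Barnard–Rubin degrees of
   freedom; CI-based candidate screening; cluster-wise and combined
   stepwise backward regressions on standardized coefficients; pooled
   adjusted R², AIC/BIC, and age/gender sensitivity refits.
5. **Planning** — effect-size conversion r = d/√(d² + 4) and minimal
   sample size for detecting a correlation under a bivariate-normal
   Fisher-z model with small-sample bias correction.
6. **Synthetic cohorts** — a generator that renders raw event streams
   whose feature–severity correlations and missingness structure are
   configurable, so every stage is testable against known ground truth.

The core pooled quantity is Rubin's total variance
`T = W + (1 + 1/m) B` with Barnard–Rubin degrees of freedom; adjusted
R² is `1 − (1 − R²)(n − 1)/(n − p − 1)`, pooled on a transformed scale.
See `vignettes/phenoframe-methods.Rmd` for the full model account.

## Worked example

Generate a small cohort with a known screen-use effect, run the whole
pipeline, and recover it:

```r
library(phenoframe)

cfg <- cohort_config(n_participants = 60, seed = 42,
                     sensors = c("screen", "ema"),
                     effect_map = list(screen_duration_mean = 0.4,
                                       ema_valence = -0.55),
                     missing_rate_day = 0.15)
coh <- generate_cohort(cfg)
feats <- extract_day_features(coh, sensors = c("screen", "ema"))
analysis <- apply_exclusion(select_best_episode(
  build_episodes(coh$phq8, feats)))
day_tab <- episode_day_table(analysis$episodes)
stack <- impute_pmm(day_tab, imputation_spec(m = 5, iterations = 5,
                                             seed = 1))
epi <- aggregate_stack(stack)

pooled_correlation(epi, "mean_screen_duration_mean")
#> 0.4260 (95% CI 0.1807 to 0.6214), df = 51.1, m = 5

sc <- screen_candidates(epi, features = paste0("mean_", c(
  "screen_duration_mean", "screen_episode_count", "ema_valence",
  "ema_stress", "ema_sleep", "ema_arousal")))
sc[, c("feature", "cluster", "r", "lo", "hi", "candidate")]
#>                       feature cluster      r    lo    hi candidate
#> lo2          mean_ema_valence     EMA -0.588 -0.74 -0.39      TRUE
#> lo3           mean_ema_stress     EMA  0.129 -0.13  0.38     FALSE
#> lo5          mean_ema_arousal     EMA -0.122 -0.37  0.14     FALSE
#> lo4            mean_ema_sleep     EMA -0.066 -0.32  0.20     FALSE
#> lo  mean_screen_duration_mean  screen  0.426  0.18  0.62      TRUE
#> lo1 mean_screen_episode_count  screen -0.049 -0.30  0.21     FALSE

mr <- stepwise_backward(epi, sc$feature[sc$candidate], label = "demo")
mr
#> [demo] adj R2 = 37.83% (17.81 to 56.96), AIC 146.7, BIC 155.1
#>   mean_ema_valence             beta -0.499 (-0.721 to -0.278)
#>   mean_screen_duration_mean    beta +0.248 (0.022 to 0.473)
```

The pooled correlation of episode-mean screen duration with the PHQ-8
sum recovers the injected 0.4 within its CI despite 15% of sensor-days
being dropped and re-imputed; screening flags exactly the two features
that carry injected effects; and the stepwise model retains both, with
standardized coefficients of the right signs and the pooled adjusted R²
on the percent scale.

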