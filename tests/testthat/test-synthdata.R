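test_that("configuration validation catches bad inputs", {
  expect_error(cohort_config(0), "count")
  expect_error(cohort_config(5, days_per_participant = 10), ">= 14")
  expect_error(cohort_config(5, episodes_per_participant = 2,
                             days_per_participant = 14), "14 days")
  expect_error(cohort_config(5, missing_rate_day = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(5, effect_map = list(not_a_feature = 0.3)),
               "unknown feature")
  expect_error(cohort_config(5, effect_map = list(ema_valence = -0.99)),
               "<= 0.95")
})

test_that("same seed gives a byte-identical cohort", {
  cfg <- cohort_config(3, seed = 42, sensors = c("screen", "calls", "ema"),
                       effect_map = list(ema_valence = -0.4),
                       missing_rate_day = 0.1, missing_rate_ema = 0.1)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("generated values respect their domains", {
  cfg <- cohort_config(3, seed = 5)
  coh <- generate_cohort(cfg)
  expect_true(all(coh$ema$value >= 0 & coh$ema$value <= 100))
  items <- as.matrix(coh$phq8[, paste0("item", 1:8)])
  expect_true(all(items %in% 0:3))
  expect_true(all(coh$calls$duration_s >= 0))
  expect_true(all(abs(coh$gps$lat) <= 90))
  expect_true(all(abs(coh$gps$lon) <= 180))
  expect_true(all(coh$screen$state %in% c("unlock", "lock")))
})

test_that("PHQ-8 item generator hits its expectation and limits", {
  set.seed(1)
  expect_equal(generate_phq8_items(0), rep(0L, 8))
  expect_equal(generate_phq8_items(24), rep(3L, 8))
  sums <- replicate(1e4, sum(generate_phq8_items(12)))
  expect_gte(mean(sums), 11); expect_lte(mean(sums), 13)
  expect_true(all(replicate(50, generate_phq8_items(7)) %in% 0:3))
  expect_error(generate_phq8_items(25), "\\[0, 24\\]")
})

test_that("null effect map gives near-zero feature-severity correlations", {
  s <- sim_day_with_outcome(500, effect_map = list(
    screen_duration_mean = 0, ema_valence = 0), seed = 31)
  ag <- aggregate_to_episode(s$day)
  for (f in c("mean_screen_duration_mean", "mean_ema_valence")) {
    r <- cor(ag[[f]], ag$phq8_sum)
    expect_lt(abs(r), 2 / sqrt(500 - 3) * 1.5)
  }
})

test_that("injected correlations are recovered within Monte-Carlo error", {
  targets <- list(screen_duration_mean = 0.4, ema_valence = -0.55,
                  call_incoming_count = 0.25)
  s <- sim_day_with_outcome(500, effect_map = targets, seed = 17)
  ag <- aggregate_to_episode(s$day)
  for (f in names(targets)) {
    r_hat <- cor(ag[[paste0("mean_", f)]], ag$phq8_sum)
    tol <- 2 * (1 - targets[[f]]^2) / sqrt(500)
    expect_lt(abs(r_hat - targets[[f]]), tol)
  }
})

test_that("severity distribution matches the configured profile", {
  set.seed(2)
  s <- phenoframe:::draw_severity(20000, 5.8, 4.4)
  expect_true(all(s >= 0 & s <= 24))
  # truncation at 24 pulls the realized moments slightly below target
  expect_equal(mean(s), 5.8, tolerance = 0.03)
  expect_gt(sd(s), 3.9); expect_lt(sd(s), 4.5)
  expect_gt(mean((s - mean(s))^3) / sd(s)^3, 0.5)  # right-skew
})

test_that("rendered event streams reproduce injected daily feature values", {
  cfg <- cohort_config(4, seed = 23, sensors = c("screen", "ema"),
                       effect_map = list(screen_duration_mean = 0.5))
  coh <- generate_cohort(cfg)
  df <- extract_day_features(coh, sensors = c("screen", "ema"))
  # no missingness configured -> no missing cells in any computed column
  expect_equal(sum(is.na(df)), 0)
  expect_equal(nrow(df), 4 * 14)
})

test_that("day dropout and EMA non-response produce missing day features", {
  cfg <- cohort_config(6, seed = 77, sensors = c("screen", "ema"),
                       missing_rate_day = 0.3, missing_rate_ema = 0.3)
  coh <- generate_cohort(cfg)
  df <- extract_day_features(coh, sensors = c("screen", "ema"))
  expect_lt(nrow(df), 6 * 14 + 1)  # some full days may vanish
  expect_gt(sum(is.na(df$screen_duration_mean)) + (6 * 14 - nrow(df)), 0)
})

test_that("MNAR slope makes higher-severity participants lose more days", {
  cfg2 <- cohort_config(40, seed = 3, sensors = "screen",
                        missing_rate_day = 0.25, dropout_mnar_slope = 2)
  coh2 <- generate_cohort(cfg2)
  per_pid <- tapply(as.Date(coh2$screen$timestamp),
                    coh2$screen$participant_id,
                    function(d) length(unique(d)))
  sev <- coh2$participants$severity[
    match(names(per_pid), coh2$participants$participant_id)]
  expect_lt(cor(sev, as.numeric(per_pid)), 0)
})

test_that("cohort csv round trip preserves the extracted features", {
  cfg <- cohort_config(2, seed = 9, sensors = c("screen", "calls", "ema"),
                       effect_map = list(ema_stress = 0.3))
  coh <- generate_cohort(cfg)
  dir <- tempfile("cohort")
  on.exit(unlink(dir, recursive = TRUE))
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  coh2 <- read_cohort(dir)
  f1 <- extract_day_features(coh, sensors = c("screen", "calls", "ema"))
  f2 <- extract_day_features(coh2, sensors = c("screen", "calls", "ema"))
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("infeasible correlation targets are rejected", {
  cfg <- cohort_config(30, seed = 1, sensors = "ema",
                       effect_map = list(ema_valence = -0.95))
  expect_error(generate_cohort(cfg), "infeasible")
})
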