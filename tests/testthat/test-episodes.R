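# Episode assembly, missingness accounting, selection, and exclusion.

mk_day_features <- function(pid, dates, f1, f2, f3) {
  data.frame(participant_id = pid, date = dates, f1 = f1, f2 = f2,
             f3 = f3)
}

mk_phq8 <- function(pid, date, items = c(2, 1, 0, 1, 2, 0, 1, 1)) {
  out <- data.frame(participant_id = pid, date = as.Date(date))
  for (i in 1:8) out[[paste0("item", i)]] <- items[i]
  out
}

test_that("one episode per PHQ-8 response over the trailing 14 days", {
  dates <- as.Date("2022-01-03") + 0:27
  dfeat <- mk_day_features("p1", dates, 1, 2, 3)
  phq <- rbind(mk_phq8("p1", "2022-01-16"), mk_phq8("p1", "2022-01-30"))
  eps <- build_episodes(phq, dfeat)
  expect_equal(nrow(eps), 2)
  expect_equal(eps$phq8_sum, c(8, 8))
  expect_equal(eps$missingness, c(0, 0))
  # a participant with no PHQ-8 never appears
  dfeat2 <- rbind(dfeat, mk_day_features("p2", dates, 1, 1, 1))
  eps2 <- build_episodes(phq, dfeat2)
  expect_false("p2" %in% eps2$participant_id)
})

test_that("missingness counts cells over 14 days x counted features", {
  dates <- as.Date("2022-01-03") + 0:13
  # 7 of 14 days fully absent
  dfeat <- mk_day_features("p1", dates[1:7], 1, 2, 3)
  eps <- build_episodes(mk_phq8("p1", "2022-01-16"), dfeat)
  expect_equal(eps$missingness, 0.5)
  # 3 features, 21 missing cells -> 0.5
  f1 <- c(rep(NA, 7), rep(1, 7))
  f2 <- c(rep(1, 7), rep(NA, 7))
  f3 <- c(rep(NA, 7), rep(1, 7))
  dfeat2 <- mk_day_features("p1", dates, f1, f2, f3)
  eps2 <- build_episodes(mk_phq8("p1", "2022-01-16"), dfeat2)
  expect_equal(eps2$missingness, 21 / 42)
  expect_equal(episode_missingness(dfeat2, c("f1", "f2", "f3")), 0.5)
  expect_error(episode_missingness(dfeat2, character(0)), "empty")
  expect_error(build_episodes(mk_phq8("p1", "2022-01-16",
                                      items = c(4, 0, 0, 0, 0, 0, 0, 0)),
                              dfeat2), "\\{0, 1, 2, 3\\}")
})

test_that("partially answered PHQ-8 forms are dropped", {
  dates <- as.Date("2022-01-03") + 0:13
  dfeat <- mk_day_features("p1", dates, 1, 2, 3)
  phq <- mk_phq8("p1", "2022-01-16")
  phq$item3 <- NA
  eps <- build_episodes(rbind(phq, mk_phq8("p2", "2022-01-16")),
                        rbind(dfeat,
                              mk_day_features("p2", dates, 1, 1, 1)))
  expect_equal(eps$participant_id, "p2")
})

test_that("best-episode selection minimizes missingness, earliest on tie", {
  eps <- structure(
    data.frame(participant_id = c("p1", "p1", "p1", "p2", "p2"),
               phq8_date = as.Date(c("2022-01-16", "2022-02-01",
                                     "2022-02-15", "2022-02-01",
                                     "2022-01-16")),
               phq8_sum = c(5, 5, 5, 7, 7),
               missingness = c(0.4, 0.1, 0.3, 0.2, 0.2)),
    class = c("episode_set", "data.frame"))
  best <- select_best_episode(eps)
  expect_equal(nrow(best), 2)
  expect_equal(best$missingness[best$participant_id == "p1"], 0.1)
  # tie at 0.2 -> earlier date
  expect_equal(best$phq8_date[best$participant_id == "p2"],
               as.Date("2022-01-16"))
})

test_that("exclusion removes >50% missingness strictly", {
  eps <- structure(
    data.frame(participant_id = c("p1", "p2", "p3"),
               phq8_date = as.Date("2022-01-16") + 0:2,
               phq8_sum = c(5, 7, 9),
               missingness = c(0.51, 0.50, 0.10)),
    class = c("episode_set", "data.frame"))
  res <- apply_exclusion(eps)
  expect_equal(res$n_before, 3)
  expect_equal(res$n_after, 2)
  expect_equal(res$excluded, "p1")
  expect_true(all(c("p2", "p3") %in% res$episodes$participant_id))
  # no participant retained twice
  expect_false(any(duplicated(res$episodes$participant_id)))
})

test_that("episode day table has 14 rows per participant with NA fills", {
  dates <- as.Date("2022-01-03") + 0:13
  dfeat <- mk_day_features("p1", dates[1:10], 1, 2, 3)
  eps <- build_episodes(mk_phq8("p1", "2022-01-16"), dfeat)
  best <- select_best_episode(eps)
  dt <- episode_day_table(best)
  expect_equal(nrow(dt), 14)
  expect_equal(sum(is.na(dt$f1)), 4)
  expect_true(all(dt$phq8_sum == 8))
})

test_that("raising day dropout cannot reduce exclusions (fixed seeds)", {
  run <- function(rate) {
    cfg <- cohort_config(12, seed = 55, sensors = "ema",
                         missing_rate_ema = rate)
    coh <- generate_cohort(cfg)
    df <- extract_day_features(coh, sensors = "ema")
    # participants whose days vanished entirely still need day rows
    eps <- build_episodes(coh$phq8, df)
    sum(select_best_episode(eps)$missingness > 0.5)
  }
  expect_lte(run(0.3), run(0.85))
})

test_that("descriptives report the share above the clinical cutoff", {
  eps <- data.frame(participant_id = sprintf("p%03d", 1:107),
                    phq8_sum = c(rep(15, 20), rep(4, 87)))
  d <- phq8_descriptives(eps)
  expect_equal(d$n, 107)
  expect_equal(d$n_above_cutoff, 20)
  expect_equal(round(d$pct_above_cutoff, 1), 18.7)
})

test_that("analysis sets round-trip to episodes.csv and exclusions.json", {
  eps <- structure(
    data.frame(participant_id = c("p1", "p2", "p3"),
               phq8_date = as.Date("2022-01-16") + 0:2,
               phq8_sum = c(5, 7, 9),
               missingness = c(0.6, 0.2, 0.1)),
    class = c("episode_set", "data.frame"))
  res <- apply_exclusion(eps)
  dir <- tempfile("an")
  on.exit(unlink(dir, recursive = TRUE))
  write_analysis_set(res, dir)
  back <- read.csv(file.path(dir, "episodes.csv"))
  expect_equal(nrow(back), 2)
  exc <- jsonlite::read_json(file.path(dir, "exclusions.json"))
  expect_equal(exc$n_excluded, 1)
  expect_equal(unlist(exc$excluded), "p1")
})
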