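# Synthetic cohort generator: latent severity, event-stream rendering,
# and the day-level statistical simulator.

#' Features whose severity correlation can be injected
#'
#' The renderer realizes these features' daily values exactly in the
#' emitted event streams, so a configured between-person correlation with
#' severity survives feature extraction.
#'
#' @return Character vector of feature names accepted in `effect_map`.
#' @export
injectable_features <- function() {
  c(paste0("ema_", ema_items()),
    "screen_duration_mean", "screen_episode_count",
    "app_count", "app_duration_mean",
    "call_incoming_count", "call_outgoing_count")
}

# Generating parameters per injectable feature: participant-level base,
# between-person SD, day-level (within-person) SD, bounds, and extra
# per-observation noise that averages into the daily value (EMA prompts).
feature_params <- function(name) {
  ema_base <- c(valence = 66, arousal = 50, stress = 39, sleep = 60,
                social_quality = 60, social_quantity = 55, nutrition = 60,
                physical_activity = 50)
  if (startsWith(name, "ema_")) {
    it <- sub("^ema_", "", name)
    return(list(base = unname(ema_base[it]), sd_b = 13, sd_w = 7,
                lo = 2, hi = 98, obs_sd = 4, obs_n = 3, integer = FALSE))
  }
  p <- switch(name,
    screen_duration_mean = list(base = 0.10, sd_b = 0.030, sd_w = 0.015,
                                lo = 0.01, hi = 0.25),
    screen_episode_count = list(base = 40, sd_b = 9, sd_w = 5,
                                lo = 5, hi = 75, integer = TRUE),
    app_count = list(base = 60, sd_b = 14, sd_w = 8, lo = 8, hi = 110,
                     integer = TRUE),
    app_duration_mean = list(base = 0.05, sd_b = 0.015, sd_w = 0.008,
                             lo = 0.005, hi = 0.10),
    call_incoming_count = list(base = 4, sd_b = 1.2, sd_w = 1,
                               lo = 1, hi = 9, integer = TRUE),
    call_outgoing_count = list(base = 4, sd_b = 1.2, sd_w = 1,
                               lo = 1, hi = 9, integer = TRUE),
    list(base = 0, sd_b = 1, sd_w = 0.5, lo = -Inf, hi = Inf))
  p$obs_sd <- p$obs_sd %||% 0
  p$obs_n <- p$obs_n %||% 1
  p$integer <- isTRUE(p$integer)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort generator configuration
#'
#' Validates and assembles the configuration of the synthetic cohort.
#' `effect_map` gives, per feature, the target between-person Pearson
#' correlation of the feature's 14-day mean with the PHQ-8 sum; the
#' generator inflates the latent loading to offset the attenuation from
#' day-level noise and PHQ-8 item discretization, so the target is the
#' correlation you should recover downstream.
#'
#' @param n_participants Number of participants (>= 1).
#' @param days_per_participant Days of data per participant (>= 14, and
#'   >= 14 * episodes_per_participant).
#' @param episodes_per_participant PHQ-8 responses per participant.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @param effect_map Named list/vector: feature name -> target correlation
#'   in \[-0.95, 0.95\]. Names must be in
#'   \code{\link{injectable_features}}. Empty map = all-null cohort.
#' @param missing_rate_day Probability a participant-day's sensor streams
#'   are dropped.
#' @param missing_rate_ema Probability an EMA prompt goes unanswered.
#' @param dropout_mnar_slope Log-odds increase of day dropout per SD of
#'   severity (0 = MCAR).
#' @param tz Timezone for all emitted timestamps (single fixed zone).
#' @param start_date First day of data collection.
#' @param gps_interval_min Minutes between GPS fixes.
#' @param sensors Which event streams to render (default all five);
#'   streams left out are returned as NULL. EMA and PHQ-8 are always
#'   generated when listed / by design respectively.
#' @param severity_mean,severity_sd Target mean/SD of the latent severity
#'   (0-24 scale); defaults give the right-skewed subclinical profile
#'   (mean 5.8, SD 4.4).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants,
                          days_per_participant = 14L,
                          episodes_per_participant = 1L,
                          seed = 1L,
                          effect_map = list(),
                          missing_rate_day = 0,
                          missing_rate_ema = 0,
                          dropout_mnar_slope = 0,
                          tz = "UTC",
                          start_date = as.Date("2022-01-03"),
                          gps_interval_min = 10,
                          sensors = c("screen", "app", "calls", "gps",
                                      "ema"),
                          severity_mean = 5.8,
                          severity_sd = 4.4) {
  sensors <- match.arg(sensors, several.ok = TRUE)
  if (!is_count(n_participants)) stopf("n_participants must be a count")
  if (!is_count(days_per_participant) || days_per_participant < 14)
    stopf("days_per_participant must be an integer >= 14")
  if (!is_count(episodes_per_participant))
    stopf("episodes_per_participant must be a count")
  if (days_per_participant < 14 * episodes_per_participant)
    stopf("need at least 14 days per episode")
  for (p in c(missing_rate_day, missing_rate_ema))
    if (p < 0 || p > 1) stopf("missing rates must lie in [0, 1]")
  em <- as.list(effect_map)
  if (length(em)) {
    bad <- setdiff(names(em), injectable_features())
    if (length(bad))
      stopf("unknown feature name(s) in effect_map: %s",
            paste(bad, collapse = ", "))
    r <- unlist(em)
    if (any(abs(r) > 0.95))
      stopf("|target correlation| must be <= 0.95")
  }
  structure(list(n_participants = as.integer(n_participants),
                 days_per_participant = as.integer(days_per_participant),
                 episodes_per_participant =
                   as.integer(episodes_per_participant),
                 seed = as.integer(seed), effect_map = em,
                 missing_rate_day = missing_rate_day,
                 missing_rate_ema = missing_rate_ema,
                 dropout_mnar_slope = dropout_mnar_slope,
                 tz = tz, start_date = as.Date(start_date),
                 gps_interval_min = gps_interval_min, sensors = sensors,
                 severity_mean = severity_mean,
                 severity_sd = severity_sd),
            class = "cohort_config")
}

#' Effect map patterned on a typical subclinical smartphone-sensing study
#'
#' Convenience defaults: negative loadings for positive-affect EMA items,
#' positive loadings for stress and screen use.
#'
#' @return Named list usable as `effect_map` in
#'   \code{\link{cohort_config}}.
#' @export
default_effect_map <- function() {
  list(ema_valence = -0.55, ema_social_quality = -0.51, ema_sleep = -0.50,
       ema_arousal = -0.42, ema_social_quantity = -0.39,
       ema_nutrition = -0.25, ema_stress = 0.42,
       screen_duration_mean = 0.37)
}

# Draw latent severities: gamma matched to the target mean/SD, truncated
# to [0, 24] by resampling the tail.
draw_severity <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  rate <- mean / sd^2
  s <- rgamma(n, shape = shape, rate = rate)
  while (any(s > 24)) s[s > 24] <- rgamma(sum(s > 24), shape, rate)
  s
}

# Attenuation of a between-person correlation by PHQ-8 item
# discretization: items are Binomial(3, s/24), so the conditional
# variance of the sum is s (1 - s/24). Uses the configured population
# moments of severity (E[s (1 - s/24)] = mean - (sd^2 + mean^2)/24) so
# the calibration is stable at any cohort size.
phq8_attenuation <- function(mean_sev, sd_sev) {
  v_b <- sd_sev^2
  v_w <- mean_sev - (sd_sev^2 + mean_sev^2) / 24
  sqrt(v_b / (v_b + v_w))
}

# Attenuation of a feature's correlation by day-level noise averaged over
# `days` days (plus per-observation noise averaged over obs_n draws/day).
feature_attenuation <- function(fp, days) {
  v_w <- fp$sd_w^2 + fp$obs_sd^2 / fp$obs_n
  sqrt(fp$sd_b^2 / (fp$sd_b^2 + v_w / days))
}

# Latent feature scores: for each feature, an n-vector with population
# correlation `rho` with the standardized severity z.
latent_scores <- function(z, effect_map, lambda_phq, days) {
  feats <- names(effect_map)
  out <- list()
  for (f in feats) {
    fp <- feature_params(f)
    lam <- feature_attenuation(fp, days) * lambda_phq
    rho <- effect_map[[f]] / lam
    if (abs(rho) > 0.95)
      stopf(paste0("infeasible correlation for '%s': target %.2f needs ",
                   "latent loading %.2f after attenuation"),
            f, effect_map[[f]], rho)
    out[[f]] <- rho * z + sqrt(1 - rho^2) * rnorm(length(z))
  }
  out
}

#' Generate PHQ-8 item scores from a latent severity
#'
#' Each of the 8 items is an independent Binomial(3, severity / 24) draw,
#' so the item sum has expectation equal to the latent severity and the
#' zero-noise limits are exact (severity 0 -> all items 0, severity 24 ->
#' all items 3). Uses the current RNG stream.
#'
#' @param severity Latent severity in \[0, 24\].
#' @return Integer vector of 8 item scores in \{0, 1, 2, 3\}.
#' @export
generate_phq8_items <- function(severity) {
  if (!is.numeric(severity) || length(severity) != 1L ||
      severity < 0 || severity > 24)
    stopf("severity must be a single value in [0, 24]")
  rbinom(8L, size = 3L, prob = severity / 24)
}

# Daily target values for one feature across participants x days.
# Returns n x days matrix.
daily_values <- function(score, fp, days) {
  n <- length(score)
  p_i <- clamp(fp$base + fp$sd_b * score, fp$lo, fp$hi)
  v <- matrix(p_i, n, days) + matrix(rnorm(n * days, sd = fp$sd_w), n, days)
  v <- clamp(v, fp$lo, fp$hi)
  if (fp$integer) v <- round(v)
  v
}

# Place `n` non-overlapping episodes of duration `dur_h` hours in a day,
# one per equal slot with uniform jitter. Returns start hours.
slot_starts <- function(n, dur_h) {
  slot <- 24 / n
  dur_h <- min(dur_h, 0.9 * slot)
  (seq_len(n) - 1) * slot + runif(n, 0, slot - dur_h)
}

polar_offset <- function(lat, lon, dist_km, bearing) {
  dlat <- dist_km * cos(bearing) / 111.195
  dlon <- dist_km * sin(bearing) / (111.195 * cos(lat * pi / 180))
  c(lat + dlat, lon + dlon)
}

# Three anchor points (home / work / other) with pairwise separation
# >= 0.55 km.
draw_anchors <- function() {
  home <- c(48 + runif(1, -2, 2), 11 + runif(1, -2, 2))
  repeat {
    work <- polar_offset(home[1], home[2], runif(1, 1, 3),
                         runif(1, 0, 2 * pi))
    other <- polar_offset(home[1], home[2], runif(1, 0.8, 2),
                          runif(1, 0, 2 * pi))
    d <- c(haversine_km(home[1], home[2], work[1], work[2]),
           haversine_km(home[1], home[2], other[1], other[2]),
           haversine_km(work[1], work[2], other[1], other[2]))
    if (all(d >= 0.55)) return(rbind(home = home, work = work,
                                     other = other))
  }
}

# Daily anchor schedule in hours: list of (anchor index, start, end);
# gaps are transits.
anchor_schedule <- function() {
  rbind(c(1, 0.0, 8.5), c(2, 9.0, 12.5), c(3, 13.0, 15.0),
        c(2, 15.5, 17.5), c(1, 18.0, 24.0))
}

# GPS fixes for one participant-day: anchored stays plus linear transits,
# Gaussian jitter sigma = 25 m.
render_gps_day <- function(anchors, day0, interval_min) {
  sched <- anchor_schedule()
  t_h <- seq(0, 24 - 1e-9, by = interval_min / 60)
  lat <- lon <- numeric(length(t_h))
  for (i in seq_along(t_h)) {
    h <- t_h[i]
    row <- which(sched[, 2] <= h & h < sched[, 3])
    if (length(row)) {
      a <- anchors[sched[row[1], 1], ]
      lat[i] <- a[1]; lon[i] <- a[2]
    } else {
      nxt <- which(sched[, 2] > h)[1]
      prv <- nxt - 1L
      f <- (h - sched[prv, 3]) / (sched[nxt, 2] - sched[prv, 3])
      a0 <- anchors[sched[prv, 1], ]; a1 <- anchors[sched[nxt, 1], ]
      lat[i] <- a0[1] + f * (a1[1] - a0[1])
      lon[i] <- a0[2] + f * (a1[2] - a0[2])
    }
  }
  sj <- 0.025 / 111.195
  lat <- lat + rnorm(length(lat), sd = sj)
  lon <- lon + rnorm(length(lon), sd = sj / cos(mean(lat) * pi / 180))
  data.frame(timestamp = day0 + t_h * 3600, lat = lat, lon = lon)
}

#' Generate a synthetic smartphone-sensing cohort
#'
#' Draws a latent severity per participant from a right-skewed
#' (truncated-gamma) distribution, injects the configured feature-severity
#' correlations at the level of per-participant 14-day feature means
#' (inflating latent loadings to offset day-level noise and PHQ-8
#' discretization attenuation), renders raw event streams whose extracted
#' features realize those daily values, and applies the missingness model.
#' Fully deterministic given `config$seed`.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return Object of class `cohort`: list with data.frames `screen`
#'   (participant_id, timestamp, state), `app` (participant_id, app_id,
#'   start, end), `calls` (participant_id, timestamp, direction,
#'   contact_hash, duration_s), `gps` (participant_id, timestamp, lat,
#'   lon), `ema` (participant_id, timestamp, slot, item, value), `phq8`
#'   (participant_id, date, item1..item8), `participants` (participant_id,
#'   severity, age, gender), plus `truth` (effect map and anchor counts)
#'   and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_participants
  days <- config$days_per_participant
  tz <- config$tz
  dates <- config$start_date + seq_len(days) - 1L
  day0 <- as.numeric(as.POSIXct(paste(dates, "00:00:00"), tz = tz))
  pids <- sprintf("p%03d", seq_len(n))

  sev <- draw_severity(n, config$severity_mean, config$severity_sd)
  z <- as.numeric(scale(sev))
  lam_phq <- phq8_attenuation(config$severity_mean, config$severity_sd)
  age <- round(clamp(18 + rgamma(n, shape = 1.2, rate = 0.25), 18, 70))
  gender <- ifelse(runif(n) < 0.78, "female", "male")

  # every injectable feature gets daily values; non-mapped ones are null
  all_feats <- injectable_features()
  em <- setNames(as.list(rep(0, length(all_feats))), all_feats)
  for (f in names(config$effect_map)) em[[f]] <- config$effect_map[[f]]
  scores <- latent_scores(z, em, lam_phq, days = 14)
  vals <- lapply(all_feats, function(f)
    daily_values(scores[[f]], feature_params(f), days))
  names(vals) <- all_feats

  # day dropout (possibly MNAR in severity)
  if (config$missing_rate_day > 0) {
    p_drop <- plogis(qlogis(config$missing_rate_day) +
                       config$dropout_mnar_slope * z)
    drop_day <- matrix(runif(n * days), n, days) <
      matrix(p_drop, n, days)
  } else drop_day <- matrix(FALSE, n, days)

  screen_l <- app_l <- calls_l <- gps_l <- ema_l <- phq8_l <- list()
  anchors_l <- list()

  for (i in seq_len(n)) {
    pid <- pids[i]
    anchors <- draw_anchors()
    anchors_l[[pid]] <- anchors
    contacts <- sprintf("%s_c%02d", pid, 1:8)
    app_pool <- sprintf("app%02d", 1:8)
    zipf <- (1 / seq_len(8)^runif(1, 0.6, 1.4))
    zipf <- zipf / sum(zipf)

    sensors <- config$sensors %||% c("screen", "app", "calls", "gps",
                                     "ema")
    for (d in seq_len(days)) {
      # EMA prompts are drawn regardless of sensor-day dropout
      if ("ema" %in% sensors) for (sl in seq_along(c(9, 14, 20))) {
        slot_h <- c(9, 14, 20)[sl]
        answered <- runif(1) >= config$missing_rate_ema
        if (!answered) next
        for (it in ema_items()) {
          f <- paste0("ema_", it)
          v <- clamp(vals[[f]][i, d] + rnorm(1, sd = feature_params(f)$obs_sd),
                     0, 100)
          ema_l[[length(ema_l) + 1L]] <- data.frame(
            participant_id = pid,
            timestamp = day0[d] + slot_h * 3600, slot = sl,
            item = it, value = v)
        }
      }
      if (drop_day[i, d]) next

      # screen
      if ("screen" %in% sensors) {
      n_sc <- max(1L, as.integer(vals$screen_episode_count[i, d]))
      d_sc <- vals$screen_duration_mean[i, d]
      st <- slot_starts(n_sc, d_sc)
      dur <- min(d_sc, 0.9 * 24 / n_sc)
      screen_l[[length(screen_l) + 1L]] <- data.frame(
        participant_id = pid,
        timestamp = rep(day0[d], 2 * n_sc) +
          as.vector(rbind(st, st + dur)) * 3600,
        state = rep(c("unlock", "lock"), n_sc))
      }

      # apps
      if ("app" %in% sensors) {
      n_ap <- max(1L, as.integer(vals$app_count[i, d]))
      d_ap <- vals$app_duration_mean[i, d]
      sta <- slot_starts(n_ap, d_ap)
      dura <- min(d_ap, 0.9 * 24 / n_ap)
      app_l[[length(app_l) + 1L]] <- data.frame(
        participant_id = pid,
        app_id = sample(app_pool, n_ap, replace = TRUE, prob = zipf),
        start = day0[d] + sta * 3600,
        end = day0[d] + (sta + dura) * 3600)
      }

      # calls
      if ("calls" %in% sensors) {
      for (dir in c("incoming", "outgoing")) {
        nc <- max(1L, as.integer(vals[[paste0("call_", dir, "_count")]][i, d]))
        calls_l[[length(calls_l) + 1L]] <- data.frame(
          participant_id = pid,
          timestamp = day0[d] + sort(runif(nc, 7, 22)) * 3600,
          direction = dir,
          contact_hash = sample(contacts, nc, replace = TRUE),
          duration_s = round(30 + rexp(nc, rate = 1 / 180)))
      }
      n_ms <- rpois(1, 0.7)
      if (n_ms > 0)
        calls_l[[length(calls_l) + 1L]] <- data.frame(
          participant_id = pid,
          timestamp = day0[d] + sort(runif(n_ms, 7, 22)) * 3600,
          direction = "missed",
          contact_hash = sample(contacts, n_ms, replace = TRUE),
          duration_s = 0)
      }

      # gps
      if ("gps" %in% sensors) {
        g <- render_gps_day(anchors, day0[d], config$gps_interval_min)
        g <- cbind(participant_id = pid, g)
        gps_l[[length(gps_l) + 1L]] <- g
      }
    }

    # PHQ-8 responses
    for (k in seq_len(config$episodes_per_participant)) {
      items <- generate_phq8_items(sev[i])
      phq8_l[[length(phq8_l) + 1L]] <- data.frame(
        participant_id = pid, date = dates[14 + 14 * (k - 1L)],
        t(setNames(items, paste0("item", 1:8))))
    }
  }

  as_posix <- function(df, cols) {
    for (cl in cols) df[[cl]] <- as.POSIXct(df[[cl]],
                                            origin = "1970-01-01", tz = tz)
    df
  }
  bindl <- function(l) if (length(l)) do.call(rbind, l) else NULL
  structure(list(
    screen = as_posix(bindl(screen_l), "timestamp"),
    app = as_posix(bindl(app_l), c("start", "end")),
    calls = as_posix(bindl(calls_l), "timestamp"),
    gps = as_posix(bindl(gps_l), "timestamp"),
    ema = as_posix(bindl(ema_l), "timestamp"),
    phq8 = bindl(phq8_l),
    participants = data.frame(participant_id = pids, severity = sev,
                              age = age, gender = gender),
    truth = list(effect_map = config$effect_map, n_anchors = 3L,
                 anchors = anchors_l,
                 lambda_phq = lam_phq),
    config = config), class = "cohort")
}

#' Simulate a day-level feature table directly (no event rendering)
#'
#' Statistical twin of \code{\link{generate_cohort}} +
#' \code{\link{extract_day_features}} for features in the injectable set:
#' draws the same latent structure and daily values but skips the event
#' renderer, which makes large replication studies (imputation coverage,
#' model-structure recovery) cheap. Missing cells are punched MCAR at the
#' given rate.
#'
#' @param n_participants Number of participants.
#' @param effect_map Named feature -> target correlation map (may include
#'   zero entries for null features).
#' @param days Days per participant (default 14).
#' @param missing_rate Per-cell MCAR missingness probability.
#' @param seed Integer seed.
#' @return List: `day` (participant_id, date, feature columns with NAs),
#'   `phq8` (participant_id, date, item1..8), `participants` (severity,
#'   age, gender).
#' @export
simulate_day_table <- function(n_participants, effect_map, days = 14L,
                               missing_rate = 0, seed = 1L) {
  set.seed(seed)
  n <- n_participants
  feats <- names(effect_map)
  sev <- draw_severity(n, 5.8, 4.4)
  z <- as.numeric(scale(sev))
  lam_phq <- phq8_attenuation(5.8, 4.4)
  scores <- latent_scores(z, effect_map, lam_phq, days = days)
  day <- data.frame(
    participant_id = rep(sprintf("p%03d", seq_len(n)), each = days),
    date = rep(as.Date("2022-01-03") + seq_len(days) - 1L, n))
  for (f in feats) {
    fp <- feature_params(f)
    v <- daily_values(scores[[f]], fp, days)
    if (fp$obs_sd > 0)  # daily value observed as mean of obs_n noisy draws
      v <- v + matrix(rnorm(n * days, sd = fp$obs_sd / sqrt(fp$obs_n)),
                      n, days)
    day[[f]] <- as.vector(t(v))
  }
  if (missing_rate > 0) {
    for (f in feats) {
      miss <- runif(nrow(day)) < missing_rate
      day[[f]][miss] <- NA_real_
    }
  }
  items <- t(vapply(sev, generate_phq8_items, integer(8)))
  colnames(items) <- paste0("item", 1:8)
  phq8 <- data.frame(participant_id = sprintf("p%03d", seq_len(n)),
                     date = as.Date("2022-01-03") + days - 1L, items)
  list(day = day, phq8 = phq8,
       participants = data.frame(
         participant_id = sprintf("p%03d", seq_len(n)), severity = sev,
         age = round(clamp(18 + rgamma(n, 1.2, 0.25), 18, 70)),
         gender = ifelse(runif(n) < 0.78, "female", "male")))
}

#' Write a cohort to delimited-text files
#'
#' Writes screen_events.csv, app_events.csv, calls.csv, gps.csv, ema.csv,
#' phq8.csv (UTF-8, header row, RFC-4180 quoting via
#' \code{utils::write.csv}) plus a ground-truth sidecar truth.json with
#' per-participant severity and the injected effect map.
#'
#' @param cohort A `cohort` from \code{\link{generate_cohort}}.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- "%Y-%m-%dT%H:%M:%OS6"
  w <- function(df, file, tcols = character(0)) {
    if (is.null(df)) return(invisible(NULL))
    for (cl in tcols) df[[cl]] <- format(df[[cl]], fmt)
    write.csv(df, file.path(dir, file), row.names = FALSE)
  }
  w(cohort$screen, "screen_events.csv", "timestamp")
  w(cohort$app, "app_events.csv", c("start", "end"))
  w(cohort$calls, "calls.csv", "timestamp")
  w(cohort$gps, "gps.csv", "timestamp")
  w(cohort$ema, "ema.csv", "timestamp")
  w(cohort$phq8, "phq8.csv")
  w(cohort$participants, "participants.csv")
  jsonlite::write_json(
    list(severity = setNames(as.list(cohort$participants$severity),
                             cohort$participants$participant_id),
         effect_map = cohort$truth$effect_map,
         n_anchors = cohort$truth$n_anchors),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort from delimited-text files
#'
#' Inverse of \code{\link{write_cohort}}; accepts the same schema for
#' real exports.
#'
#' @param dir Directory containing the CSV files.
#' @param tz Timezone used to parse timestamps.
#' @return A `cohort`-like list usable by
#'   \code{\link{extract_day_features}}.
#' @export
read_cohort <- function(dir, tz = "UTC") {
  rd <- function(file, tcols = character(0)) {
    path <- file.path(dir, file)
    if (!file.exists(path)) return(NULL)
    df <- read.csv(path, stringsAsFactors = FALSE)
    for (cl in tcols)
      df[[cl]] <- as.POSIXct(df[[cl]], format = "%Y-%m-%dT%H:%M:%OS",
                             tz = tz)
    df
  }
  phq8 <- rd("phq8.csv")
  if (!is.null(phq8)) phq8$date <- as.Date(phq8$date)
  structure(list(screen = rd("screen_events.csv", "timestamp"),
                 app = rd("app_events.csv", c("start", "end")),
                 calls = rd("calls.csv", "timestamp"),
                 gps = rd("gps.csv", "timestamp"),
                 ema = rd("ema.csv", "timestamp"),
                 phq8 = phq8,
                 participants = rd("participants.csv"),
                 config = list(tz = tz)), class = "cohort")
}
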