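# Call, app, and EMA day-level features.

#' Per-direction call features for one participant-day
#'
#' Counts and distinct contacts for incoming, outgoing, and missed calls;
#' duration mean/sum/max (hours) and duration-share entropy for incoming
#' and outgoing calls only. A day with no calls in a direction has count
#' and distinct 0 and missing duration/entropy features.
#'
#' @param direction Character vector: "incoming", "outgoing", "missed".
#' @param contact_hash Contact identifiers (any hashable vector).
#' @param duration_s Call durations in seconds (>= 0; ignored for missed).
#' @return Named list of call features.
#' @export
call_features <- function(direction, contact_hash, duration_s) {
  if (!all(direction %in% c("incoming", "outgoing", "missed")))
    stopf("call direction must be incoming/outgoing/missed")
  if (any(duration_s < 0, na.rm = TRUE)) stopf("call durations must be >= 0")
  out <- list()
  for (dir in c("incoming", "outgoing", "missed")) {
    i <- direction == dir
    out[[paste0("call_", dir, "_count")]] <- sum(i)
    out[[paste0("call_", dir, "_distinct")]] <-
      length(unique(contact_hash[i]))
    if (dir == "missed") next
    if (any(i)) {
      dh <- duration_s[i] / 3600
      out[[paste0("call_", dir, "_duration_mean")]] <- mean(dh)
      out[[paste0("call_", dir, "_duration_sum")]] <- sum(dh)
      out[[paste0("call_", dir, "_duration_max")]] <- max(dh)
      out[[paste0("call_", dir, "_entropy")]] <-
        if (sum(dh) > 0) shannon_entropy(dh) else NA_real_
    } else {
      out[[paste0("call_", dir, "_duration_mean")]] <- NA_real_
      out[[paste0("call_", dir, "_duration_sum")]] <- NA_real_
      out[[paste0("call_", dir, "_duration_max")]] <- NA_real_
      out[[paste0("call_", dir, "_entropy")]] <- NA_real_
    }
  }
  out
}

#' App usage features for one participant-day
#'
#' @param app_id App identifier per foreground episode.
#' @param duration_h Episode durations in hours.
#' @return Named list: `app_count` (number of foreground episodes),
#'   `app_duration_mean` (hours), `app_freq_entropy` (Shannon entropy of
#'   per-app episode counts). No usage: count 0, others missing.
#' @export
app_features <- function(app_id, duration_h) {
  n <- length(app_id)
  if (n == 0L)
    return(list(app_count = 0L, app_duration_mean = NA_real_,
                app_freq_entropy = NA_real_))
  counts <- table(app_id)
  list(app_count = n,
       app_duration_mean = mean(duration_h),
       app_freq_entropy = shannon_entropy(as.numeric(counts)))
}

# Window-level app regularity: dominant (longest-duration) app per hour.
app_regularity <- function(app_eps, dates, tz) {
  if (is.null(app_eps) || !nrow(app_eps) || length(dates) < 2L)
    return(NA_real_)
  occ <- list()  # app -> days x 24 duration matrix
  day0 <- as.numeric(as.POSIXct(paste(dates, "00:00:00"), tz = tz))
  apps <- unique(app_eps$app_id)
  arr <- array(0, dim = c(length(dates), 24L, length(apps)))
  s <- as.numeric(app_eps$start); e <- as.numeric(app_eps$end)
  for (i in seq_len(nrow(app_eps))) {
    ai <- match(app_eps$app_id[i], apps)
    for (di in seq_along(dates)) {
      a <- max(s[i], day0[di]); b <- min(e[i], day0[di] + 86400)
      if (b <= a) next
      h0 <- (a - day0[di]) / 3600; h1 <- (b - day0[di]) / 3600
      for (h in floor(h0):min(23, ceiling(h1) - 1)) {
        ov <- min(h1, h + 1) - max(h0, h)
        if (ov > 0) arr[di, h + 1L, ai] <- arr[di, h + 1L, ai] + ov
      }
    }
  }
  dom <- matrix("none", nrow = length(dates), ncol = 24L)
  for (di in seq_along(dates)) for (h in 1:24) {
    o <- arr[di, h, ]
    if (any(o > 0)) dom[di, h] <- as.character(apps[which.max(o)])
  }
  regularity_index(dom)
}

#' Daily EMA aggregates for one participant-day
#'
#' Mean of the answered prompts per item; items with no answered prompt
#' that day are missing.
#'
#' @param item Item name per response (e.g. "valence").
#' @param value Response value on the 0-100 scale.
#' @param items Full set of item names to report (missing when absent).
#' @return Named list `ema_<item>` of daily means.
#' @export
ema_daily <- function(item, value, items = ema_items()) {
  if (any(value < 0 | value > 100, na.rm = TRUE))
    stopf("EMA values must lie in [0, 100]")
  out <- setNames(as.list(rep(NA_real_, length(items))),
                  paste0("ema_", items))
  for (it in intersect(unique(item), items))
    out[[paste0("ema_", it)]] <- mean(value[item == it], na.rm = TRUE)
  out
}

#' EMA item names
#' @return Character vector of the eight EMA items.
#' @export
ema_items <- function() {
  c("valence", "arousal", "stress", "sleep", "social_quality",
    "social_quantity", "nutrition", "physical_activity")
}
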