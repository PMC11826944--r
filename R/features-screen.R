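# Screen sessionization and per-day screen features.

#' Pair screen lock/unlock events into unlock episodes
#'
#' Walks a time-sorted event stream for one participant and pairs each
#' unlock with the next lock. Malformed sequences are resolved
#' conservatively: a second unlock while an episode is open closes the
#' open episode at the second unlock (zero-gap policy) and starts a new
#' one; a lock with no open episode is dropped; an episode left open at
#' the end of the stream is dropped.
#'
#' @param time POSIXct event times, sorted ascending.
#' @param state Character vector, "unlock" or "lock", same length.
#' @return data.frame with POSIXct columns `start`, `end` (end >= start),
#'   non-overlapping and time-ordered.
#' @export
sessionize_screen <- function(time, state) {
  if (length(time) != length(state)) stopf("time/state length mismatch")
  if (is.unsorted(as.numeric(time))) {
    o <- order(time)
    time <- time[o]; state <- state[o]
  }
  if (!all(state %in% c("unlock", "lock")))
    stopf("screen states must be 'unlock' or 'lock'")
  starts <- ends <- numeric(0)
  open <- NA_real_
  tt <- as.numeric(time)
  for (i in seq_along(tt)) {
    if (state[i] == "unlock") {
      if (!is.na(open)) { starts <- c(starts, open); ends <- c(ends, tt[i]) }
      open <- tt[i]
    } else {
      if (!is.na(open)) { starts <- c(starts, open); ends <- c(ends, tt[i]) }
      open <- NA_real_
    }
  }
  tz <- attr(time, "tzone")
  if (is.null(tz)) tz <- "UTC"
  data.frame(start = as.POSIXct(starts, origin = "1970-01-01", tz = tz),
             end = as.POSIXct(ends, origin = "1970-01-01", tz = tz))
}

# Split [start, end] intervals at local midnights; returns one row per
# (interval segment, date) with duration in hours. Conserves total
# duration. `id`, when given, is carried through to the segments.
clip_to_days <- function(start, end, tz, id = NULL) {
  s <- as.numeric(start); e <- as.numeric(end)
  day <- as.Date(as.POSIXct(s, origin = "1970-01-01", tz = tz), tz = tz)
  day_end <- as.numeric(as.POSIXct(paste(day + 1L, "00:00:00"), tz = tz))
  inside <- e <= day_end
  res <- data.frame(date = day[inside], start = s[inside],
                    end = e[inside])
  out_id <- which(inside)
  # slow path: episodes crossing one or more midnights
  for (i in which(!inside)) {
    a <- s[i]
    d <- day[i]
    repeat {
      nxt <- as.numeric(as.POSIXct(paste(d + 1L, "00:00:00"), tz = tz))
      b <- min(e[i], nxt)
      res <- rbind(res, data.frame(date = d, start = a, end = b))
      out_id <- c(out_id, i)
      if (e[i] <= nxt) break
      a <- nxt
      d <- d + 1L
    }
  }
  res$hours <- (res$end - res$start) / 3600
  if (!is.null(id)) res$id <- id[out_id]
  res
}

# Hours of "on" time per (date, hour-of-day) from clipped segments.
hour_on_matrix <- function(segs, dates, tz) {
  mat <- matrix(0, nrow = length(dates), ncol = 24L,
                dimnames = list(as.character(dates), NULL))
  if (nrow(segs)) {
    for (i in seq_len(nrow(segs))) {
      di <- match(as.character(segs$date[i]), rownames(mat))
      if (is.na(di)) next
      day0 <- as.numeric(as.POSIXct(paste(segs$date[i], "00:00:00"), tz = tz))
      h0 <- (segs$start[i] - day0) / 3600
      h1 <- (segs$end[i] - day0) / 3600
      for (h in floor(h0):min(23, ceiling(h1) - 1)) {
        ov <- min(h1, h + 1) - max(h0, h)
        if (ov > 0) mat[di, h + 1L] <- mat[di, h + 1L] + ov
      }
    }
  }
  mat
}

# Per-day screen features for one participant. `episodes` from
# sessionize_screen. Returns data.frame keyed by date.
screen_day_features <- function(episodes, tz) {
  if (!nrow(episodes)) {
    return(data.frame(date = as.Date(character(0)),
                      screen_episode_count = integer(0),
                      screen_duration_sum = numeric(0),
                      screen_duration_mean = numeric(0),
                      screen_duration_max = numeric(0),
                      screen_entropy = numeric(0),
                      screen_norm_entropy = numeric(0)))
  }
  segs <- clip_to_days(episodes$start, episodes$end, tz)
  sp <- split(segs, segs$date)
  rows <- lapply(names(sp), function(dt) {
    s <- sp[[dt]]
    on <- sum(s$hours)
    off <- max(0, 24 - on)
    data.frame(date = as.Date(dt),
               screen_episode_count = nrow(s),
               screen_duration_sum = on,
               screen_duration_mean = mean(s$hours),
               screen_duration_max = max(s$hours),
               screen_entropy = shannon_entropy(c(on, off)),
               screen_norm_entropy = normalized_entropy(c(on, off)))
  })
  do.call(rbind, rows)
}

# Window-level screen regularity: dominant state per hour = "on" if the
# unlocked share of the hour exceeds one half, else "off".
screen_regularity <- function(episodes, dates, tz) {
  if (!nrow(episodes) || length(dates) < 2L) return(NA_real_)
  segs <- clip_to_days(episodes$start, episodes$end, tz)
  occ <- hour_on_matrix(segs, dates, tz)
  regularity_index(ifelse(occ > 0.5, "on", "off"))
}
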