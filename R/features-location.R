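# GPS motion classification, significant-place clustering, and the
# day-level and window-level location features.

#' Classify GPS fixes into moving and static states
#'
#' Speed between consecutive fixes is the haversine distance divided by
#' the elapsed time; a fix is labelled "moving" when the speed of the
#' segment ending at it exceeds 1 km/h and "static" otherwise (exactly
#' 1 km/h counts as static). The first fix inherits the state of the
#' first segment. Duplicate timestamps are deduplicated (first kept).
#'
#' @param time POSIXct fix times, sorted ascending.
#' @param lat,lon Coordinates in decimal degrees.
#' @return data.frame `time`, `lat`, `lon`, `state` ("moving"/"static"),
#'   `speed_kmh` (NA for the first fix of a single-fix trace).
#' @export
classify_motion <- function(time, lat, lon) {
  keep <- !duplicated(as.numeric(time))
  time <- time[keep]; lat <- lat[keep]; lon <- lon[keep]
  n <- length(time)
  if (n == 0L)
    return(data.frame(time = time, lat = lat, lon = lon,
                      state = character(0), speed_kmh = numeric(0)))
  if (n == 1L)
    return(data.frame(time = time, lat = lat, lon = lon,
                      state = "static", speed_kmh = NA_real_))
  dt_h <- diff(as.numeric(time)) / 3600
  dist <- haversine_km(lat[-n], lon[-n], lat[-1], lon[-1])
  sp <- dist / dt_h
  state <- c(ifelse(sp[1] > 1, "moving", "static"),
             ifelse(sp > 1, "moving", "static"))
  data.frame(time = time, lat = lat, lon = lon, state = state,
             speed_kmh = c(sp[1], sp))
}

# Maximal runs of >= 2 consecutive static fixes ("pauses"); returns one
# row per pause: centroid, start/end (numeric seconds), dwell hours.
# Runs are additionally split where consecutive fixes are more than
# `max_gap_h` apart (whereabouts unknown across a recording gap).
extract_pauses <- function(motion, max_gap_h = 1) {
  st <- motion$state == "static"
  if (!any(st)) return(NULL)
  gap <- c(FALSE, diff(as.numeric(motion$time)) / 3600 > max_gap_h)
  run_id <- cumsum(c(TRUE, diff(st) != 0L) | gap)
  r <- list(lengths = as.integer(table(run_id)),
            values = st[!duplicated(run_id)])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 2L
  if (!any(keep)) return(NULL)
  idx <- which(keep)
  out <- lapply(idx, function(k) {
    i <- starts[k]:ends[k]
    data.frame(lat = mean(motion$lat[i]), lon = mean(motion$lon[i]),
               t0 = as.numeric(motion$time[i[1]]),
               t1 = as.numeric(motion$time[i[length(i)]]),
               dwell = (as.numeric(motion$time[i[length(i)]]) -
                          as.numeric(motion$time[i[1]])) / 3600)
  })
  do.call(rbind, out)
}

# Iterative k-means over pause centroids: k grows from 1 while all
# inter-centroid haversine distances stay >= `min_sep_km`; the largest
# valid k is kept. Returns list(centers, assignment) with assignment NA
# for pauses farther than `visit_km` from every centroid (outliers).
cluster_pauses <- function(pauses, min_sep_km = 0.4, visit_km = 0.2) {
  pts <- cbind(pauses$lat, pauses$lon)
  upts <- unique(pts)
  kmax <- nrow(upts)
  best <- matrix(colMeans(pts), ncol = 2)
  if (kmax > 1L) {
    for (k in 2:kmax) {
      if (k == kmax) {
        ctr <- upts
      } else {
        fit <- with_local_seed(k * 1000L + nrow(pts), {
          tryCatch(kmeans(pts, centers = k, nstart = 5, iter.max = 50),
                   error = function(e) NULL)
        })
        if (is.null(fit)) break
        ctr <- fit$centers
      }
      pair_ok <- TRUE
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        if (haversine_km(ctr[i, 1], ctr[i, 2], ctr[j, 1], ctr[j, 2]) <
            min_sep_km) pair_ok <- FALSE
      }
      if (!pair_ok) break
      best <- ctr
    }
  }
  d <- sapply(seq_len(nrow(best)), function(j)
    haversine_km(pauses$lat, pauses$lon, best[j, 1], best[j, 2]))
  d <- matrix(d, nrow = nrow(pauses))
  nearest <- max.col(-d, ties.method = "first")
  mind <- d[cbind(seq_len(nrow(d)), nearest)]
  assignment <- ifelse(mind <= visit_km, nearest, NA_integer_)
  list(centers = best, assignment = assignment)
}

#' Cluster static GPS pauses into significant places
#'
#' Pauses (maximal runs of at least two static fixes) are clustered by
#' k-means with k increased while all centroids remain at least 400 m
#' apart; pauses within 200 m of a centroid count as visits, others as
#' outliers; clusters with at least 10 minutes total dwell are flagged
#' significant.
#'
#' @param motion Output of \code{\link{classify_motion}}.
#' @param min_sep_km Minimum centroid separation (default 0.4 km).
#' @param visit_km Maximum pause-to-centroid distance for a visit
#'   (default 0.2 km).
#' @param sig_dwell_h Dwell threshold for significance (default 10 min).
#' @return List with `clusters` (data.frame: cluster_id, lat, lon,
#'   total_dwell, visit_count, significant), `pauses` (with assignment),
#'   and the scalar features described in
#'   \code{\link{extract_day_features}}; NULL if there are no pauses.
#' @export
cluster_places <- function(motion, min_sep_km = 0.4, visit_km = 0.2,
                           sig_dwell_h = 10 / 60) {
  pauses <- extract_pauses(motion)
  if (is.null(pauses)) return(NULL)
  cl <- cluster_pauses(pauses, min_sep_km, visit_km)
  k <- nrow(cl$centers)
  dwell <- vapply(seq_len(k), function(j)
    sum(pauses$dwell[cl$assignment == j], na.rm = TRUE), numeric(1))
  visits <- vapply(seq_len(k), function(j)
    sum(cl$assignment == j, na.rm = TRUE), integer(1))
  sig <- dwell >= sig_dwell_h
  clusters <- data.frame(cluster_id = seq_len(k),
                         lat = cl$centers[, 1], lon = cl$centers[, 2],
                         total_dwell = dwell, visit_count = visits,
                         significant = sig)
  sig_dwell <- dwell[sig]
  top <- sort(sig_dwell, decreasing = TRUE)
  assigned <- cl$assignment[!is.na(cl$assignment)]
  n_trans <- if (length(assigned) >= 2L) sum(diff(assigned) != 0L) else 0L
  outlier_dwell <- sum(pauses$dwell[is.na(cl$assignment)])
  feats <- list(
    n_significant_clusters = sum(sig),
    stay_duration_mean = if (length(sig_dwell)) mean(sig_dwell) else NA_real_,
    stay_duration_max = if (length(sig_dwell)) max(sig_dwell) else NA_real_,
    stay_duration_sd = if (length(sig_dwell) >= 2L) sd(sig_dwell) else
      if (length(sig_dwell) == 1L) 0 else NA_real_,
    time_top1 = if (length(top) >= 1L) top[1] else NA_real_,
    time_top2 = if (length(top) >= 2L) top[2] else NA_real_,
    time_top3 = if (length(top) >= 3L) top[3] else NA_real_,
    location_entropy = if (length(sig_dwell) && sum(sig_dwell) > 0)
      shannon_entropy(sig_dwell) else NA_real_,
    location_norm_entropy = if (length(sig_dwell) >= 2L)
      normalized_entropy(sig_dwell) else NA_real_,
    n_transitions = n_trans,
    outlier_time_ratio = if (sum(sig_dwell) > 0)
      outlier_dwell / sum(sig_dwell) else NA_real_)
  c(list(clusters = clusters,
         pauses = cbind(pauses, cluster = cl$assignment)), feats)
}

#' Log combined variance of latitude and longitude
#'
#' ln(var(lat) + var(lon)) with population (1/n) variances in squared
#' degrees. NA when the combined variance is zero or fewer than 2 fixes.
#'
#' @param lat,lon Coordinates in decimal degrees.
#' @return Log combined variance, or NA.
#' @export
location_variance <- function(lat, lon) {
  n <- length(lat)
  if (n < 2L) return(NA_real_)
  pv <- function(x) mean((x - mean(x))^2)
  v <- pv(lat) + pv(lon)
  if (v <= 0) return(NA_real_)
  log(v)
}

# Lomb-Scargle periodogram power of series x at angular frequency w.
lomb_power <- function(t, x, w) {
  x <- x - mean(x)
  v <- mean(x^2)
  if (v <= 0) return(rep(NA_real_, length(w)))
  vapply(w, function(wk) {
    tau <- atan2(sum(sin(2 * wk * t)), sum(cos(2 * wk * t))) / (2 * wk)
    ct <- cos(wk * (t - tau)); st <- sin(wk * (t - tau))
    (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2)) / (2 * v)
  }, numeric(1))
}

#' Circadian movement of a GPS trace
#'
#' Least-squares (Lomb-Scargle) spectral power of the latitude and
#' longitude series in the 23.5-24.5 h period band, averaged over the
#' evaluated frequencies, summed over the two axes and log-transformed.
#' High values indicate location patterns that repeat on a 24-hour
#' rhythm (daily routine); NA when the trace spans fewer than 2 days or
#' has no spatial variance.
#'
#' @param time POSIXct fix times.
#' @param lat,lon Coordinates in decimal degrees.
#' @param n_freq Number of frequencies evaluated in the band (default 24).
#' @return ln(E_lat + E_lon), or NA.
#' @export
circadian_movement <- function(time, lat, lon, n_freq = 24L) {
  t_h <- (as.numeric(time) - min(as.numeric(time))) / 3600
  if (length(t_h) < 4L || diff(range(t_h)) < 48) return(NA_real_)
  periods <- seq(23.5, 24.5, length.out = n_freq)
  w <- 2 * pi / periods
  e_lat <- lomb_power(t_h, lat, w)
  e_lon <- lomb_power(t_h, lon, w)
  if (all(is.na(e_lat)) && all(is.na(e_lon))) return(NA_real_)
  band <- function(e) if (all(is.na(e))) 0 else mean(e, na.rm = TRUE)
  tot <- band(e_lat) + band(e_lon)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  log(tot)
}

#' Location routine index over a multi-day window
#'
#' Regularity index (\code{\link{regularity_index}}) of the dominant
#' significant-cluster occupancy per hour of day: for each day and hour
#' the state is the cluster occupying most of that hour, or "away" when
#' no cluster dwell falls in it. Clusters are determined once over the
#' whole window so that cluster identities are comparable across days.
#'
#' @param motion Output of \code{\link{classify_motion}} for the window.
#' @param dates Vector of dates forming the window.
#' @param tz Timezone for day/hour boundaries.
#' @return Value in \[0, 1\], or NA (fewer than 2 days or no pauses).
#' @export
location_routine_index <- function(motion, dates, tz) {
  if (length(dates) < 2L) return(NA_real_)
  cp <- cluster_places(motion)
  if (is.null(cp)) return(NA_real_)
  p <- cp$pauses
  p <- p[!is.na(p$cluster), , drop = FALSE]
  if (!nrow(p)) return(NA_real_)
  occ <- array(0, dim = c(length(dates), 24L, nrow(cp$clusters)))
  day0 <- as.numeric(as.POSIXct(paste(dates, "00:00:00"), tz = tz))
  for (i in seq_len(nrow(p))) {
    for (di in seq_along(dates)) {
      a <- max(p$t0[i], day0[di]); b <- min(p$t1[i], day0[di] + 86400)
      if (b <= a) next
      h0 <- (a - day0[di]) / 3600; h1 <- (b - day0[di]) / 3600
      for (h in floor(h0):min(23, ceiling(h1) - 1)) {
        ov <- min(h1, h + 1) - max(h0, h)
        if (ov > 0) occ[di, h + 1L, p$cluster[i]] <-
            occ[di, h + 1L, p$cluster[i]] + ov
      }
    }
  }
  dom <- matrix("away", nrow = length(dates), ncol = 24L)
  for (di in seq_along(dates)) for (h in 1:24) {
    o <- occ[di, h, ]
    if (any(o > 0)) dom[di, h] <- as.character(which.max(o))
  }
  regularity_index(dom)
}
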