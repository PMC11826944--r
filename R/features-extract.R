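# Top-level day-feature extraction over a cohort of event streams.

#' Feature dictionary
#'
#' @return data.frame with one row per day-level feature: `name`,
#'   `cluster` (EMA/app/call/location/screen), `units`, and whether the
#'   feature is computed per day or once per observation window
#'   (regularity indices and circadian movement need multiple days).
#' @export
feature_dictionary <- function() {
  f <- function(name, cluster, units, level = "day")
    data.frame(name = name, cluster = cluster, units = units, level = level)
  rbind(
    f("screen_episode_count", "screen", "count"),
    f("screen_duration_sum", "screen", "hours"),
    f("screen_duration_mean", "screen", "hours"),
    f("screen_duration_max", "screen", "hours"),
    f("screen_entropy", "screen", "nats"),
    f("screen_norm_entropy", "screen", "ratio"),
    f("screen_regularity", "screen", "ratio", "window"),
    f("app_count", "app", "count"),
    f("app_duration_mean", "app", "hours"),
    f("app_freq_entropy", "app", "nats"),
    f("app_regularity", "app", "ratio", "window"),
    do.call(rbind, lapply(c("incoming", "outgoing"), function(d) rbind(
      f(paste0("call_", d, "_count"), "call", "count"),
      f(paste0("call_", d, "_distinct"), "call", "count"),
      f(paste0("call_", d, "_duration_mean"), "call", "hours"),
      f(paste0("call_", d, "_duration_sum"), "call", "hours"),
      f(paste0("call_", d, "_duration_max"), "call", "hours"),
      f(paste0("call_", d, "_entropy"), "call", "nats")))),
    f("call_missed_count", "call", "count"),
    f("call_missed_distinct", "call", "count"),
    f("total_distance", "location", "km"),
    f("location_variance", "location", "log deg^2"),
    f("moving_static_ratio", "location", "ratio"),
    f("n_significant_clusters", "location", "count"),
    f("stay_duration_mean", "location", "hours"),
    f("stay_duration_max", "location", "hours"),
    f("stay_duration_sd", "location", "hours"),
    f("time_top1", "location", "hours"),
    f("time_top2", "location", "hours"),
    f("time_top3", "location", "hours"),
    f("location_entropy", "location", "nats"),
    f("location_norm_entropy", "location", "ratio"),
    f("n_transitions", "location", "count"),
    f("outlier_time_ratio", "location", "ratio"),
    f("circadian_movement", "location", "log power", "window"),
    f("location_routine_index", "location", "ratio", "window"),
    do.call(rbind, lapply(ema_items(), function(it)
      f(paste0("ema_", it), "EMA", "0-100")))
  )
}

#' Cluster label of a feature (or episode-aggregate) name
#'
#' @param name Feature names, possibly with `mean_`/`sd_` aggregate
#'   prefixes.
#' @return Character vector: "EMA", "app", "call", "screen", "location".
#' @export
feature_cluster <- function(name) {
  base <- sub("^(mean_|sd_)", "", name)
  ifelse(startsWith(base, "ema_"), "EMA",
    ifelse(startsWith(base, "app_"), "app",
      ifelse(startsWith(base, "call_"), "call",
        ifelse(startsWith(base, "screen_"), "screen", "location"))))
}

sensor_of_cluster <- c(EMA = "ema", app = "app", call = "calls",
                       screen = "screen", location = "gps")

#' Extract the day-level feature table from raw event streams
#'
#' Computes every feature of \code{\link{feature_dictionary}} for each
#' participant-day with any recorded event. Count features are 0 on days
#' where the sensor stream has no events; duration and entropy features
#' are missing (NA) on such days, which is what the downstream
#' missingness accounting relies on. Window-level features (regularity
#' indices, location routine, circadian movement) are computed once per
#' participant over the full observed span and repeated on each day row.
#'
#' @param cohort A list with elements `screen`, `app`, `calls`, `gps`,
#'   `ema` (data.frames as produced by \code{\link{generate_cohort}} or
#'   read by \code{\link{read_cohort}}); missing elements are skipped.
#' @param sensors Which sensor groups to compute (default all present).
#' @param tz Timezone defining the local day; defaults to the cohort's
#'   configured timezone, else "UTC".
#' @return data.frame: `participant_id`, `date`, one column per feature.
#' @export
extract_day_features <- function(cohort,
                                 sensors = c("screen", "app", "calls",
                                             "gps", "ema"),
                                 tz = NULL) {
  if (is.null(tz))
    tz <- if (!is.null(cohort$config$tz)) cohort$config$tz else "UTC"
  sensors <- intersect(sensors, names(cohort)[!vapply(cohort, is.null,
                                                      logical(1))])
  if (!length(sensors)) stopf("no sensor streams present")
  dict <- feature_dictionary()
  active <- dict[dict$cluster %in%
                   names(sensor_of_cluster)[sensor_of_cluster %in% sensors], ]

  pids <- unique(unlist(lapply(sensors, function(s)
    unique(cohort[[s]]$participant_id))))
  rows <- list()
  for (pid in pids) {
    sub <- lapply(sensors, function(s) {
      d <- cohort[[s]]
      d[d$participant_id == pid, , drop = FALSE]
    })
    names(sub) <- sensors
    dates <- sort(unique(do.call(c, lapply(sensors, function(s) {
      d <- sub[[s]]
      if (!nrow(d)) return(as.Date(character(0)))
      tcol <- intersect(c("timestamp", "start"), names(d))[1]
      as.Date(d[[tcol]], tz = tz)
    }))))
    if (!length(dates)) next
    tab <- data.frame(participant_id = pid, date = dates)
    for (nm in active$name) tab[[nm]] <- NA_real_

    if ("screen" %in% sensors && nrow(sub$screen)) {
      eps <- sessionize_screen(sub$screen$timestamp, sub$screen$state)
      sdf <- screen_day_features(eps, tz)
      i <- match(sdf$date, tab$date)
      ok <- !is.na(i)
      for (nm in setdiff(names(sdf), "date"))
        tab[[nm]][i[ok]] <- sdf[[nm]][ok]
      tab$screen_episode_count[is.na(tab$screen_episode_count)] <- 0
      tab$screen_regularity <- screen_regularity(eps, dates, tz)
    }

    if ("app" %in% sensors && nrow(sub$app)) {
      segs <- clip_to_days(sub$app$start, sub$app$end, tz,
                           id = sub$app$app_id)
      segs$app_id <- segs$id
      for (dt in unique(segs$date)) {
        s <- segs[segs$date == dt, ]
        af <- app_features(s$app_id, s$hours)
        i <- match(as.Date(dt, origin = "1970-01-01"), tab$date)
        if (is.na(i)) next
        for (nm in names(af)) tab[[nm]][i] <- af[[nm]]
      }
      tab$app_count[is.na(tab$app_count)] <- 0
      tab$app_regularity <- app_regularity(
        data.frame(app_id = sub$app$app_id, start = sub$app$start,
                   end = sub$app$end), dates, tz)
    }

    if ("calls" %in% sensors) {
      cd <- sub$calls
      cdate <- if (nrow(cd)) as.Date(cd$timestamp, tz = tz) else
        as.Date(character(0))
      for (di in seq_along(dates)) {
        i <- which(cdate == dates[di])
        cf <- call_features(cd$direction[i], cd$contact_hash[i],
                            cd$duration_s[i])
        for (nm in names(cf)) tab[[nm]][di] <- cf[[nm]]
      }
    }

    if ("gps" %in% sensors && nrow(sub$gps)) {
      g <- sub$gps[order(sub$gps$timestamp), ]
      gdate <- as.Date(g$timestamp, tz = tz)
      for (di in seq_along(dates)) {
        i <- which(gdate == dates[di])
        if (length(i) < 2L) next
        mo <- classify_motion(g$timestamp[i], g$lat[i], g$lon[i])
        n <- nrow(mo)
        tab$total_distance[di] <- sum(haversine_km(
          mo$lat[-n], mo$lon[-n], mo$lat[-1], mo$lon[-1]))
        tab$location_variance[di] <- location_variance(mo$lat, mo$lon)
        n_mov <- sum(mo$state == "moving")
        n_sta <- sum(mo$state == "static")
        if (n_sta > 0) tab$moving_static_ratio[di] <- n_mov / n_sta
        cp <- cluster_places(mo)
        if (!is.null(cp)) {
          for (nm in c("n_significant_clusters", "stay_duration_mean",
                       "stay_duration_max", "stay_duration_sd",
                       "time_top1", "time_top2", "time_top3",
                       "location_entropy", "location_norm_entropy",
                       "n_transitions", "outlier_time_ratio"))
            tab[[nm]][di] <- cp[[nm]]
        }
      }
      mo_all <- classify_motion(g$timestamp, g$lat, g$lon)
      tab$circadian_movement <- circadian_movement(g$timestamp, g$lat, g$lon)
      tab$location_routine_index <- location_routine_index(mo_all, dates, tz)
    }

    if ("ema" %in% sensors && nrow(sub$ema)) {
      edate <- as.Date(sub$ema$timestamp, tz = tz)
      for (di in seq_along(dates)) {
        i <- which(edate == dates[di])
        if (!length(i)) next
        ef <- ema_daily(sub$ema$item[i], sub$ema$value[i])
        for (nm in names(ef)) tab[[nm]][di] <- ef[[nm]]
      }
    }

    rows[[length(rows) + 1L]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
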