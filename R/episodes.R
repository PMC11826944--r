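# 14-day episode assembly, eligibility filtering, and episode selection.

phq8_item_cols <- paste0("item", 1:8)

# Validate a PHQ-8 log; drops partially answered forms (any NA item).
validate_phq8 <- function(phq8) {
  items <- as.matrix(phq8[, phq8_item_cols])
  bad <- !is.na(items) & (items < 0 | items > 3 | items != round(items))
  if (any(bad))
    stopf("PHQ-8 items must lie in {0, 1, 2, 3}")
  complete <- rowSums(is.na(items)) == 0L
  phq8 <- phq8[complete, , drop = FALSE]
  phq8$phq8_sum <- rowSums(phq8[, phq8_item_cols])
  phq8
}

#' Build 14-day episodes around each PHQ-8 response
#'
#' One episode per (complete) PHQ-8 response: the completion day and the
#' 13 preceding days (the instrument's recall window). Days absent from
#' the day-feature table appear as fully missing rows. Episode-level
#' missingness is the fraction of missing cells over 14 days x the
#' counted features.
#'
#' @param phq8 PHQ-8 log: `participant_id`, `date`, `item1`..`item8`.
#'   Forms with any missing item are dropped; items outside 0..3 raise an
#'   error.
#' @param day_features Day-feature table from
#'   \code{\link{extract_day_features}} (or any table with
#'   `participant_id`, `date` and feature columns).
#' @param features Feature columns counted in the missingness fraction;
#'   defaults to every non-key column of `day_features`.
#' @return data.frame of class `episode_set`: one row per episode with
#'   `participant_id`, `phq8_date`, `phq8_sum`, `missingness`; the day
#'   table and counted features are attached as attributes for downstream
#'   extraction of day blocks.
#' @export
build_episodes <- function(phq8, day_features,
                           features = NULL) {
  phq8 <- validate_phq8(phq8)
  if (is.null(features))
    features <- setdiff(names(day_features), c("participant_id", "date"))
  if (!length(features)) stopf("empty feature list")
  eps <- lapply(seq_len(nrow(phq8)), function(i) {
    pid <- phq8$participant_id[i]
    d1 <- as.Date(phq8$date[i])
    block_dates <- seq(d1 - 13L, d1, by = "day")
    rows <- day_features[day_features$participant_id == pid &
                           day_features$date %in% block_dates, ,
                         drop = FALSE]
    n_missing <- 14L * length(features) -
      sum(!is.na(as.matrix(rows[, features, drop = FALSE])))
    data.frame(participant_id = pid, phq8_date = d1,
               phq8_sum = phq8$phq8_sum[i],
               missingness = n_missing / (14L * length(features)))
  })
  out <- do.call(rbind, eps)
  attr(out, "day_features") <- day_features
  attr(out, "features") <- features
  class(out) <- c("episode_set", "data.frame")
  out
}

#' Episode missingness fraction
#'
#' Missing cells divided by 14 x number of counted features, counting
#' EMA and sensing columns equally; days with no row count as fully
#' missing.
#'
#' @param day_block Day rows of one episode (up to 14).
#' @param features Counted feature columns (non-empty).
#' @return Fraction in \[0, 1\].
#' @export
episode_missingness <- function(day_block, features) {
  if (!length(features)) stopf("empty feature list")
  present <- sum(!is.na(as.matrix(day_block[, features, drop = FALSE])))
  1 - present / (14L * length(features))
}

#' Select the lowest-missingness episode per participant
#'
#' Ties are broken by the earliest PHQ-8 date.
#'
#' @param episodes An `episode_set` from \code{\link{build_episodes}}.
#' @return `episode_set` with one row per participant.
#' @export
select_best_episode <- function(episodes) {
  o <- order(episodes$participant_id, episodes$missingness,
             episodes$phq8_date)
  e <- episodes[o, , drop = FALSE]
  keep <- !duplicated(e$participant_id)
  out <- e[keep, , drop = FALSE]
  for (a in c("day_features", "features"))
    attr(out, a) <- attr(episodes, a)
  class(out) <- class(episodes)
  out
}

#' Apply the >50% missingness exclusion
#'
#' Removes participants whose selected episode has strictly more than
#' 50\% missing cells (a fraction of exactly 0.5 is retained).
#'
#' @param episodes One episode per participant
#'   (\code{\link{select_best_episode}}).
#' @return List: `episodes` (retained `episode_set`), `n_before`,
#'   `n_after`, `n_excluded`, `excluded` (participant ids).
#' @export
apply_exclusion <- function(episodes) {
  drop <- episodes$missingness > 0.5
  kept <- episodes[!drop, , drop = FALSE]
  for (a in c("day_features", "features"))
    attr(kept, a) <- attr(episodes, a)
  class(kept) <- class(episodes)
  list(episodes = kept,
       n_before = nrow(episodes), n_after = nrow(kept),
       n_excluded = sum(drop),
       excluded = episodes$participant_id[drop])
}

#' Day-level table for the selected episodes
#'
#' Expands an episode set to its day blocks: exactly 14 rows per episode
#' (missing days filled with NA features), with `phq8_sum` attached to
#' every row as the episode-constant (level-2) variable. This is the unit
#' of imputation.
#'
#' @param episodes An `episode_set` (one row per participant).
#' @return data.frame: `participant_id`, `date`, `phq8_sum`, features.
#' @export
episode_day_table <- function(episodes) {
  day_features <- attr(episodes, "day_features")
  features <- attr(episodes, "features")
  blocks <- lapply(seq_len(nrow(episodes)), function(i) {
    pid <- episodes$participant_id[i]
    d1 <- episodes$phq8_date[i]
    block_dates <- seq(d1 - 13L, d1, by = "day")
    skel <- data.frame(participant_id = pid, date = block_dates,
                       phq8_sum = episodes$phq8_sum[i])
    rows <- day_features[day_features$participant_id == pid &
                           day_features$date %in% block_dates, ,
                         drop = FALSE]
    for (f in features)
      skel[[f]] <- rows[[f]][match(block_dates, rows$date)]
    skel
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Cohort descriptives for an analysis set
#'
#' @param episodes Retained episodes (one per participant).
#' @param cutoff PHQ-8 severity cutoff (default 10).
#' @return List: `n`, `mean`, `sd`, `n_above_cutoff`,
#'   `pct_above_cutoff` (percent).
#' @export
phq8_descriptives <- function(episodes, cutoff = 10) {
  s <- episodes$phq8_sum
  list(n = length(s), mean = mean(s), sd = sd(s),
       n_above_cutoff = sum(s >= cutoff),
       pct_above_cutoff = 100 * mean(s >= cutoff))
}

#' Write an analysis set to delimited text
#'
#' Writes `episodes.csv` (one row per retained participant) and
#' `exclusions.json` (counts and excluded ids).
#'
#' @param analysis Result of \code{\link{apply_exclusion}}.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis_set <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eps <- as.data.frame(analysis$episodes)
  write.csv(eps[, c("participant_id", "phq8_date", "phq8_sum",
                    "missingness")],
            file.path(dir, "episodes.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_before = analysis$n_before, n_after = analysis$n_after,
         n_excluded = analysis$n_excluded,
         excluded = analysis$excluded,
         reason = "episode missingness > 0.5"),
    file.path(dir, "exclusions.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
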