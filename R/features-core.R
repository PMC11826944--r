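#' Shannon entropy of a frequency vector (nats)
#'
#' Entropy of the normalized frequency distribution, -sum p_i ln p_i with
#' p_i = f_i / sum(f). Zero frequencies contribute nothing. Used for all
#' behavioral entropy features (app frequency, call duration shares,
#' screen state occupancy, cluster dwell shares).
#'
#' @param freq Non-negative numeric vector with at least one positive entry.
#' @return Entropy in nats (>= 0).
#' @examples
#' shannon_entropy(c(1, 1, 1, 1))  # log(4)
#' shannon_entropy(c(3, 1))        # ~0.5623
#' @export
shannon_entropy <- function(freq) {
  if (!is.numeric(freq) || length(freq) == 0L || any(is.na(freq)) ||
      any(freq < 0))
    stopf("`freq` must be non-negative numeric")
  tot <- sum(freq)
  if (tot <= 0) stopf("entropy undefined: all frequencies are zero")
  p <- freq[freq > 0] / tot
  -sum(p * log(p))
}

#' Normalized Shannon entropy
#'
#' Entropy divided by log of the number of states N (the length of the
#' frequency vector), giving a value in \[0, 1\]. Undefined (NA) for fewer
#' than two states.
#'
#' @inheritParams shannon_entropy
#' @return Value in \[0, 1\], or NA if fewer than 2 states.
#' @export
normalized_entropy <- function(freq) {
  n_states <- length(freq)
  if (n_states < 2L) return(NA_real_)
  shannon_entropy(freq) / log(n_states)
}

#' Regularity index of an hourly state schedule
#'
#' Similarity of behavior between the same hours across days: the mean,
#' over all unordered pairs of days, of the fraction of the 24 hours whose
#' dominant state agrees between the two days. 1 means an identical daily
#' schedule; values near 0 mean no hour-of-day structure. Shared by the
#' screen, app, and location-routine variants.
#'
#' @param state_mat Matrix (days x 24) of dominant states per hour
#'   (character or integer; NA is treated as its own "none" state).
#' @return Value in \[0, 1\], or NA with fewer than 2 days.
#' @export
regularity_index <- function(state_mat) {
  if (is.null(dim(state_mat)) || ncol(state_mat) != 24L)
    stopf("`state_mat` must be a days x 24 matrix")
  d <- nrow(state_mat)
  if (d < 2L) return(NA_real_)
  m <- matrix(as.character(state_mat), nrow = d)
  m[is.na(m)] <- ".none."
  agree <- 0
  npair <- 0L
  for (i in seq_len(d - 1L)) for (j in (i + 1L):d) {
    agree <- agree + mean(m[i, ] == m[j, ])
    npair <- npair + 1L
  }
  agree / npair
}

#' Great-circle (haversine) distance
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorized).
#' @return Distance in kilometers (Earth radius 6371 km).
#' @examples
#' haversine_km(0, 0, 1, 0)  # ~111.195
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 180, na.rm = TRUE))
    stopf("coordinates out of range: |lat| <= 90, |lon| <= 180")
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}
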