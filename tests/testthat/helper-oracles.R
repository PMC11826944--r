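# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive each quantity from first
# principles rather than calling the package's implementation.

oracle_entropy <- function(freq) {
  p <- freq / sum(freq)
  tot <- 0
  for (pi in p) if (pi > 0) tot <- tot - pi * log(pi)
  tot
}

oracle_regularity <- function(mat) {
  d <- nrow(mat)
  vals <- c()
  for (i in seq_len(d - 1)) for (j in (i + 1):d)
    vals <- c(vals, sum(mat[i, ] == mat[j, ]) / ncol(mat))
  mean(vals)
}

oracle_rubin <- function(q, u, df_com) {
  m <- length(q)
  qbar <- sum(q) / m
  W <- sum(u) / m
  B <- sum((q - qbar)^2) / (m - 1)
  Tt <- W + (1 + 1 / m) * B
  lam <- (1 + 1 / m) * B / Tt
  nu_obs <- (1 - lam) * df_com * (df_com + 1) / (df_com + 3)
  df <- if (lam > 0) {
    nu_old <- (m - 1) / lam^2
    nu_old * nu_obs / (nu_old + nu_obs)
  } else nu_obs
  list(qbar = qbar, W = W, B = B, T = Tt, df = df,
       ci = qbar + c(-1, 1) * qt(0.975, df) * sqrt(Tt))
}

# Exact normal-approximation power curve scanned over n (independent of
# the package's block search).
oracle_required_n <- function(r, power, alpha, sides) {
  for (n in 4:5000) {
    zc <- qnorm(1 - alpha / sides)
    mu <- sqrt(n - 3) * (atanh(r) + r / (2 * (n - 1)))
    pw <- pnorm(-zc - mu) + 1 - pnorm(zc - mu)  # both tails
    if (pw >= power) return(n)
  }
  NA_integer_
}

# Day table + phq8_sum column assembled from the direct simulator.
sim_day_with_outcome <- function(n, effect_map, missing_rate = 0,
                                 seed = 1) {
  s <- simulate_day_table(n, effect_map = effect_map,
                          missing_rate = missing_rate, seed = seed)
  dt <- s$day
  dt$phq8_sum <- rowSums(
    s$phq8[match(dt$participant_id, s$phq8$participant_id),
           paste0("item", 1:8)])
  list(day = dt, participants = s$participants)
}

# Aliases to internal helpers exercised directly in the unit tests.
clip_to_days_for_test <- phenoframe:::clip_to_days
screen_day_features_for_test <- phenoframe:::screen_day_features
screen_regularity_for_test <- phenoframe:::screen_regularity
app_regularity_for_test <- phenoframe:::app_regularity
extract_pauses_for_test <- phenoframe:::extract_pauses

# Wrap complete episode-level tables as a stack.
as_stack <- function(...) {
  tabs <- list(...)
  structure(tabs, class = "episode_stack", n = nrow(tabs[[1]]))
}
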