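#' Convert a standardized mean difference to a point-biserial correlation
#'
#' Maps Cohen's d (comparing two equal-sized groups) to the equivalent
#' Pearson correlation, r = d / sqrt(d^2 + 4). Used when translating
#' clinically relevant group differences into correlation-scale effect
#' sizes for sample-size planning.
#'
#' @param d Standardized mean difference (finite numeric, vectorized).
#' @return Correlation(s) in (-1, 1); odd in `d` (sign preserved).
#' @examples
#' smd_to_r(0.24)  # ~0.12
#' @export
smd_to_r <- function(d) {
  if (!is.numeric(d) || any(!is.finite(d)))
    stopf("`d` must be finite numeric")
  d / sqrt(d^2 + 4)
}

#' Inverse of smd_to_r
#'
#' @param r Correlation in (-1, 1).
#' @return Standardized mean difference d = 2 r / sqrt(1 - r^2).
#' @export
r_to_smd <- function(r) {
  if (!is.numeric(r) || any(abs(r) >= 1)) stopf("`r` must lie in (-1, 1)")
  2 * r / sqrt(1 - r^2)
}

# Power of the Fisher-z test of rho = 0 at sample size n, with the
# small-sample bias term r / (2 (n - 1)) added to the transformed effect.
# Only the tail on the side of the true effect is counted (the opposite
# tail is numerically negligible for the effect sizes of interest).
fisher_z_power <- function(n, r, alpha, sides) {
  zcrit <- qnorm(1 - alpha / sides)
  ncp <- sqrt(n - 3) * (atanh(abs(r)) + abs(r) / (2 * (n - 1)))
  pnorm(ncp - zcrit)
}

#' Required sample size to detect a Pearson correlation
#'
#' Smallest n for which the test of rho = 0 against a true correlation
#' `r` reaches the requested power, under a bivariate normal model using
#' the Fisher z approximation with small-sample bias correction
#' (the transformed effect is atanh(r) + r / (2 (n - 1)), with sampling
#' variance 1 / (n - 3)).
#'
#' @param r True correlation, in (0, 1) in absolute value (nonzero).
#' @param power Target power in (0, 1). Default 0.80.
#' @param alpha Significance level in (0, 1). Default 0.05.
#' @param sides 1 or 2 (one- or two-sided test). Default 2.
#' @param n_max Search ceiling; an error is raised if the target power is
#'   not reached below it.
#' @return Integer sample size.
#' @examples
#' required_n_correlation(0.12)             # 542
#' required_n_correlation(0.3, power = 0.9) # small n
#' @export
required_n_correlation <- function(r, power = 0.8, alpha = 0.05, sides = 2,
                                   n_max = 1e6) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r >= 1)
    stopf("`r` must be a single value in (0, 1)")
  if (power <= 0 || power >= 1) stopf("`power` must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stopf("`alpha` must be in (0, 1)")
  if (!sides %in% c(1, 2)) stopf("`sides` must be 1 or 2")
  # power is monotone increasing in n; scan in blocks
  lo <- 4L
  while (lo <= n_max) {
    hi <- min(lo + 9999L, n_max)
    ns <- lo:hi
    pw <- fisher_z_power(ns, r, alpha, sides)
    ok <- which(pw >= power)
    if (length(ok)) return(ns[ok[1L]])
    lo <- hi + 1L
  }
  stopf("target power not reachable below n_max = %g", n_max)
}
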