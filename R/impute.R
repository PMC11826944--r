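# Two-level multiple imputation by chained equations with predictive
# mean matching, and the 14-day episode aggregation.

#' Imputation specification
#'
#' @param m Number of completed datasets (default 20).
#' @param iterations Chained-equation cycles per chain (default 10).
#' @param donors Predictive-mean-matching donor pool size (default 5).
#' @param seed Integer seed; the whole stack is deterministic given it.
#' @return Object of class `imputation_spec`.
#' @export
imputation_spec <- function(m = 20L, iterations = 10L, donors = 5L,
                            seed = 1L) {
  if (!is_count(m) || m < 2) stopf("m must be an integer >= 2")
  if (!is_count(iterations)) stopf("iterations must be an integer >= 1")
  if (!is_count(donors)) stopf("donors must be an integer >= 1")
  structure(list(m = as.integer(m), iterations = as.integer(iterations),
                 donors = as.integer(donors), seed = as.integer(seed)),
            class = "imputation_spec")
}

# Moment-based random-intercept regression of y on X with grouping `g`:
# OLS for the fixed part, between/within decomposition of the residuals
# for the variance components, ICC-shrunken predicted intercepts.
# Returns a function giving (possibly perturbed) linear predictions.
ri_fit <- function(y, X, g, perturb = TRUE) {
  qrX <- qr(X)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  Xk <- X[, keep, drop = FALSE]
  fit <- lm.fit(Xk, y)
  beta <- fit$coefficients
  res <- fit$residuals
  dfr <- max(1L, length(y) - length(beta))
  sigma2 <- sum(res^2) / dfr
  XtXi <- chol2inv(chol(crossprod(Xk) + diag(1e-10, ncol(Xk))))
  # variance components from residuals
  gm <- tapply(res, g, mean)
  ng <- tapply(res, g, length)
  sig_e2 <- {
    wr <- res - gm[match(g, names(gm))]
    denom <- max(1L, length(y) - length(gm))
    sum(wr^2) / denom
  }
  sig_b2 <- max(0, var(as.numeric(gm)) - sig_e2 * mean(1 / ng))
  shrink <- sig_b2 / (sig_b2 + sig_e2 / ng)
  b_g <- setNames(as.numeric(gm) * shrink, names(gm))
  beta_star <- if (perturb) {
    L <- tryCatch(chol(sigma2 * XtXi), error = function(e) NULL)
    if (is.null(L)) beta else beta + as.numeric(t(L) %*% rnorm(length(beta)))
  } else beta
  function(Xnew, gnew) {
    b <- b_g[match(gnew, names(b_g))]
    b[is.na(b)] <- 0
    as.numeric(Xnew[, keep, drop = FALSE] %*% beta_star) + b
  }
}

# One PMM draw per missing row: uniformly among the `donors` observed
# rows with nearest predicted values.
pmm_match <- function(yhat_obs, y_obs, yhat_mis, donors) {
  k <- min(donors, length(y_obs))
  vapply(yhat_mis, function(p) {
    idx <- order(abs(yhat_obs - p))[seq_len(k)]
    y_obs[idx[sample.int(k, 1L)]]
  }, numeric(1))
}

#' Two-level predictive-mean-matching multiple imputation
#'
#' Chained-equations imputation of the day-level feature table. Per
#' incomplete variable and cycle: a random-intercept (participant-level)
#' linear model of the variable on all other variables plus the
#' episode-constant PHQ-8 sum is fitted to the observed rows (moment
#' estimator: OLS fixed part, between/within residual decomposition,
#' ICC-shrunken predicted intercepts); the fixed effects are perturbed by
#' a draw from their estimated sampling distribution; and each missing
#' row copies the observed value of one of the `donors` rows with
#' nearest prediction (uniform draw). Variables are visited in order of
#' ascending missingness; `m` independent chains are run for
#' `iterations` cycles. Observed cells are never altered. Deterministic
#' given `spec$seed`.
#'
#' @param day_table Output of \code{\link{episode_day_table}} (or any
#'   table with `participant_id`, optional `date`, complete `phq8_sum`,
#'   and numeric feature columns with NAs).
#' @param spec An \code{\link{imputation_spec}}.
#' @return Object of class `imputed_stack`: list with `tables` (m
#'   completed day tables), `traces` (chain x iteration x variable mean
#'   and SD of imputed values), `spec`, `features`.
#' @export
impute_pmm <- function(day_table, spec = imputation_spec()) {
  stopifnot(inherits(spec, "imputation_spec"))
  keys <- intersect(c("participant_id", "date", "phq8_sum"),
                    names(day_table))
  feats <- setdiff(names(day_table), keys)
  if (any(is.na(day_table$phq8_sum)))
    stopf("phq8_sum must be complete")
  nmiss <- vapply(feats, function(f) sum(is.na(day_table[[f]])),
                  integer(1))
  incomplete <- names(nmiss)[nmiss > 0]
  for (f in incomplete)
    if (sum(!is.na(day_table[[f]])) < spec$donors)
      stopf("variable '%s' has fewer observed values than donors", f)

  set.seed(spec$seed)
  g <- day_table$participant_id
  traces <- list()
  tables <- vector("list", spec$m)
  for (ch in seq_len(spec$m)) {
    tab <- day_table
    # initialize missing cells by sampling observed values
    for (f in incomplete) {
      obs <- tab[[f]][!is.na(tab[[f]])]
      mis <- is.na(tab[[f]])
      tab[[f]][mis] <- sample(obs, sum(mis), replace = TRUE)
    }
    if (length(incomplete)) {
      visit <- incomplete[order(nmiss[incomplete])]
      tr <- array(NA_real_, dim = c(spec$iterations, length(visit), 2),
                  dimnames = list(NULL, visit, c("mean", "sd")))
      for (it in seq_len(spec$iterations)) {
        for (f in visit) {
          mis <- is.na(day_table[[f]])
          preds <- setdiff(feats, f)
          X <- cbind(1, as.matrix(tab[, preds, drop = FALSE]),
                     phq8 = tab$phq8_sum)
          # drop zero-variance predictor columns (keep intercept)
          v <- apply(X, 2, var)
          X <- X[, c(TRUE, v[-1] > 0), drop = FALSE]
          fitfun <- ri_fit(day_table[[f]][!mis], X[!mis, , drop = FALSE],
                           g[!mis])
          yhat_obs <- fitfun(X[!mis, , drop = FALSE], g[!mis])
          yhat_mis <- fitfun(X[mis, , drop = FALSE], g[mis])
          imp <- pmm_match(yhat_obs, day_table[[f]][!mis], yhat_mis,
                           spec$donors)
          tab[[f]][mis] <- imp
          tr[it, f, "mean"] <- mean(imp)
          tr[it, f, "sd"] <- sd0(imp)
        }
      }
      traces[[ch]] <- tr
    }
    tables[[ch]] <- tab
  }
  structure(list(tables = tables, traces = traces, spec = spec,
                 features = feats, incomplete = incomplete),
            class = "imputed_stack")
}

#' Aggregate a completed day table to the episode level
#'
#' Per participant and feature: mean and sample SD (n-1 denominator) over
#' the 14 days; `phq8_sum` carried through unchanged. Requires exactly 14
#' complete rows per participant.
#'
#' @param day_table A completed day table.
#' @return data.frame: `participant_id`, `phq8_sum`, `mean_<f>`,
#'   `sd_<f>`.
#' @export
aggregate_to_episode <- function(day_table) {
  feats <- setdiff(names(day_table),
                   c("participant_id", "date", "phq8_sum"))
  sp <- split(day_table, day_table$participant_id)
  rows <- lapply(sp, function(b) {
    if (nrow(b) != 14L)
      stopf("participant %s has %d day rows (need 14)",
            b$participant_id[1], nrow(b))
    out <- data.frame(participant_id = b$participant_id[1],
                      phq8_sum = b$phq8_sum[1])
    for (f in feats) {
      if (any(is.na(b[[f]])))
        stopf("day table is not complete in '%s'", f)
      out[[paste0("mean_", f)]] <- mean(b[[f]])
      out[[paste0("sd_", f)]] <- sd(b[[f]])
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate every table of an imputed stack to the episode level
#'
#' @param stack An `imputed_stack`.
#' @return List of m episode-level tables (class `episode_stack`), with
#'   the number of participants as attribute `n`.
#' @export
aggregate_stack <- function(stack) {
  tabs <- lapply(stack$tables, aggregate_to_episode)
  structure(tabs, class = "episode_stack", n = nrow(tabs[[1]]))
}

#' Convergence diagnostics for an imputation run
#'
#' Per incomplete variable: the between-chain variance of the chain
#' means of imputed values at the final iteration, and a flag when the
#' mean trend over the last three iterations (averaged over chains)
#' exceeds the between-chain spread.
#'
#' @param stack An `imputed_stack`.
#' @return List: `table` (variable, between-chain SD, trend, flagged) and
#'   `note`.
#' @export
convergence_report <- function(stack) {
  if (!length(stack$incomplete))
    return(list(table = NULL, note = "complete data: nothing imputed"))
  iters <- stack$spec$iterations
  vars <- stack$incomplete
  final_means <- sapply(vars, function(f)
    vapply(stack$traces, function(tr) tr[iters, f, "mean"], numeric(1)))
  final_means <- matrix(final_means, ncol = length(vars),
                        dimnames = list(NULL, vars))
  bc_sd <- apply(final_means, 2, sd0)
  note <- if (iters < 3L) "too few iterations to assess convergence"
          else "last-3-iteration trend compared against between-chain SD"
  trend <- vapply(vars, function(f) {
    if (iters < 3L) return(NA_real_)
    tail3 <- vapply(stack$traces, function(tr)
      tr[iters, f, "mean"] - tr[iters - 2L, f, "mean"], numeric(1))
    mean(tail3)
  }, numeric(1))
  list(table = data.frame(variable = vars, between_chain_sd = bc_sd,
                          trend = trend,
                          flagged = !is.na(trend) & abs(trend) > bc_sd),
       note = note)
}

#' Write an imputed stack to delimited text
#'
#' One episode-level CSV per completed dataset (`imputed_01.csv`, ...)
#' plus `diagnostics.json` with the convergence report.
#'
#' @param stack An `imputed_stack`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_imputed_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  agg <- aggregate_stack(stack)
  for (i in seq_along(agg))
    write.csv(agg[[i]], file.path(dir, sprintf("imputed_%02d.csv", i)),
              row.names = FALSE)
  rep <- convergence_report(stack)
  jsonlite::write_json(list(m = stack$spec$m,
                            iterations = stack$spec$iterations,
                            donors = stack$spec$donors,
                            note = rep$note, table = rep$table),
                       file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
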