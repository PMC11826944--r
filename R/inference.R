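# Rubin's-rule pooling, pooled correlations, standardized regression,
# CI-driven stepwise backward elimination, and the model suite.

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines per-imputation estimates q and their variances u: pooled
#' estimate = mean(q); within-variance W = mean(u); between-variance
#' B = var(q); total T = W + (1 + 1/m) B. Degrees of freedom use the
#' Barnard-Rubin small-sample adjustment combining the classical df with
#' the complete-data df; the 95\% CI is q_bar +/- t_(df, .975) sqrt(T).
#' With m = 1 the estimate passes through with df = `df_com`.
#'
#' @param q Numeric vector of per-imputation estimates.
#' @param u Numeric vector of their variances (>= 0).
#' @param df_com Complete-data degrees of freedom.
#' @param conf Confidence level (default 0.95).
#' @return Object of class `pooled_estimate`: list with `estimate`, `W`,
#'   `B`, `T`, `df`, `ci` (lo, hi), `m`.
#' @export
rubin_pool <- function(q, u, df_com, conf = 0.95) {
  m <- length(q)
  if (length(u) != m) stopf("q and u must have equal length")
  if (any(u < 0)) stopf("variances must be >= 0")
  qbar <- mean(q)
  if (m == 1L) {
    tt <- u
    df <- df_com
  } else {
    W <- mean(u)
    B <- var(q)
    tt <- W + (1 + 1 / m) * B
    lam <- if (tt > 0) (1 + 1 / m) * B / tt else 0
    nu_obs <- (1 - lam) * df_com * (df_com + 1) / (df_com + 3)
    df <- if (lam > 0) {
      nu_old <- (m - 1) / lam^2
      nu_old * nu_obs / (nu_old + nu_obs)
    } else nu_obs
  }
  half <- qt(1 - (1 - conf) / 2, df) * sqrt(tt)
  structure(list(estimate = qbar,
                 W = if (m == 1L) u else mean(u),
                 B = if (m == 1L) 0 else var(q),
                 T = tt, df = df, m = m,
                 ci = c(lo = qbar - half, hi = qbar + half)),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("%.4f (95%% CI %.4f to %.4f), df = %.1f, m = %d\n",
              x$estimate, x$ci[1], x$ci[2], x$df, x$m))
  invisible(x)
}

# Fisher-z back-transformed pooled estimate -> r scale.
pool_fisher_z <- function(r_m, n, conf = 0.95) {
  z <- atanh(r_m)
  pooled <- rubin_pool(z, rep(1 / (n - 3), length(r_m)), df_com = n - 3,
                       conf = conf)
  pooled$estimate_r <- tanh(pooled$estimate)
  pooled$ci_r <- tanh(pooled$ci)
  pooled
}

#' Pooled between-person Pearson correlation
#'
#' Per imputed table the correlation of an episode-level feature with the
#' outcome is Fisher-z transformed (sampling variance 1 / (n - 3)),
#' pooled by \code{\link{rubin_pool}} with Barnard-Rubin df (complete-data
#' df = n - 3), and the estimate and CI are back-transformed to the r
#' scale.
#'
#' @param stack An `episode_stack` (\code{\link{aggregate_stack}}) or a
#'   plain list of episode-level data.frames.
#' @param feature Feature column name (e.g. "mean_ema_valence").
#' @param outcome Outcome column (default "phq8_sum").
#' @return A `pooled_estimate` with extra fields `estimate` / `ci` on the
#'   r scale and `degenerate` flag (|r| = 1 in any table).
#' @export
pooled_correlation <- function(stack, feature, outcome = "phq8_sum") {
  tabs <- if (inherits(stack, "imputed_stack")) stack$tables else stack
  n <- nrow(tabs[[1]])
  if (n < 4) stopf("need n >= 4")
  r_m <- vapply(tabs, function(tb) {
    x <- tb[[feature]]; y <- tb[[outcome]]
    if (var(x) == 0 || var(y) == 0)
      stopf("correlation undefined: zero variance in '%s'", feature)
    cor(x, y)
  }, numeric(1))
  if (any(abs(r_m) >= 1 - 1e-12)) {
    out <- structure(list(estimate = mean(r_m), W = 0, B = 0, T = 0,
                          df = n - 3, m = length(r_m),
                          ci = c(lo = mean(r_m), hi = mean(r_m)),
                          degenerate = TRUE),
                     class = "pooled_estimate")
    return(out)
  }
  pooled <- pool_fisher_z(r_m, n)
  pooled$estimate_z <- pooled$estimate
  pooled$ci_z <- pooled$ci
  pooled$estimate <- pooled$estimate_r
  pooled$ci <- pooled$ci_r
  pooled$degenerate <- FALSE
  pooled
}

#' Screen features for candidate predictors by pooled correlation CI
#'
#' Computes the pooled correlation of every feature with the outcome and
#' flags as candidates those whose 95\% CI excludes zero (evaluated on
#' unrounded bounds). Zero-variance features are reported with NA and
#' never flagged.
#'
#' @param stack An `episode_stack`.
#' @param features Feature columns to screen; default all `mean_` / `sd_`
#'   columns.
#' @param outcome Outcome column (default "phq8_sum").
#' @return data.frame: `feature`, `cluster`, `r`, `lo`, `hi`,
#'   `candidate`, ordered by cluster then |r| descending.
#' @export
screen_candidates <- function(stack, features = NULL,
                              outcome = "phq8_sum") {
  tabs <- unclass(stack)
  if (is.null(features))
    features <- grep("^(mean|sd)_", names(tabs[[1]]), value = TRUE)
  rows <- lapply(features, function(f) {
    zero_var <- any(vapply(tabs, function(tb) var(tb[[f]]) == 0,
                           logical(1)))
    if (zero_var)
      return(data.frame(feature = f, cluster = feature_cluster(f),
                        r = NA_real_, lo = NA_real_, hi = NA_real_,
                        candidate = FALSE))
    p <- pooled_correlation(stack, f, outcome)
    data.frame(feature = f, cluster = feature_cluster(f),
               r = p$estimate, lo = p$ci[1], hi = p$ci[2],
               candidate = !p$degenerate & (p$ci[1] > 0 | p$ci[2] < 0))
  })
  out <- do.call(rbind, rows)
  out[order(out$cluster, -abs(out$r)), ]
}

#' Standardized regression pooled across imputations
#'
#' Per imputed table, the outcome and predictors are z-scored and an OLS
#' model is fitted; each standardized coefficient is pooled by
#' \code{\link{rubin_pool}} (complete-data df = n - p - 1). The adjusted
#' R-squared, 1 - (1 - R^2)(n - 1) / (n - p - 1), is pooled on the
#' Fisher-z-of-sqrt(R^2_adj) scale (variance 1 / (n - 3)) and
#' back-transformed to the percent scale. AIC and BIC are arithmetic
#' means over tables.
#'
#' @param stack An `episode_stack`.
#' @param predictors Character vector of predictor columns (may be empty:
#'   intercept-only model reported with adjusted R^2 = 0).
#' @param outcome Outcome column (default "phq8_sum").
#' @param covariates Optional extra columns (e.g. age, gender dummy)
#'   appended unstandardized-selectable; they are z-scored too when
#'   numeric, and dichotomous character/factor columns are coded 0/1.
#' @return List: `coef` (data.frame predictor, beta, lo, hi, W, B, df),
#'   `adj_r2` (pooled estimate, percent), `aic`, `bic`, `n`, `p`.
#' @export
fit_standardized_model <- function(stack, predictors,
                                   outcome = "phq8_sum",
                                   covariates = NULL) {
  tabs <- unclass(stack)
  n <- nrow(tabs[[1]])
  all_pred <- c(predictors, names(covariates %||% list()))
  p <- length(all_pred)
  if (n <= p + 2) stopf("need n > p + 2")
  if (p == 0) {
    return(list(coef = NULL,
                adj_r2 = structure(list(estimate = 0, ci = c(lo = 0, hi = 0),
                                        df = n - 1, m = length(tabs)),
                                   class = "pooled_estimate"),
                aic = NA_real_, bic = NA_real_, n = n, p = 0L))
  }
  zscore <- function(x) {
    if (is.character(x) || is.factor(x)) x <- as.numeric(factor(x)) - 1
    if (sd(x) == 0) stopf("zero-variance predictor")
    (x - mean(x)) / sd(x)
  }
  per <- lapply(tabs, function(tb) {
    if (!is.null(covariates))
      for (nm in names(covariates)) tb[[nm]] <- covariates[[nm]]
    d <- data.frame(.y = zscore(tb[[outcome]]))
    for (nm in all_pred) d[[nm]] <- zscore(tb[[nm]])
    # collinearity guard
    Xm <- as.matrix(d[, all_pred, drop = FALSE])
    if (p >= 2) {
      ev <- eigen(crossprod(Xm) / (n - 1), symmetric = TRUE,
                  only.values = TRUE)$values
      if (min(ev) < 1e-10) {
        cc <- cor(Xm)
        diag(cc) <- 0
        worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
        stopf("collinear predictors: %s and %s",
              all_pred[worst[1]], all_pred[worst[2]])
      }
    }
    fit <- lm(.y ~ ., data = d)
    sm <- summary(fit)
    list(beta = coef(fit)[all_pred],
         se = setNames(sm$coefficients[all_pred, 2], all_pred),
         r2 = sm$r.squared, aic = AIC(fit), bic = BIC(fit))
  })
  df_com <- n - p - 1
  coefs <- lapply(all_pred, function(nm) {
    qv <- vapply(per, function(x) unname(x$beta[nm]), numeric(1))
    uv <- vapply(per, function(x) unname(x$se[nm])^2, numeric(1))
    pe <- rubin_pool(qv, uv, df_com = df_com)
    data.frame(predictor = nm, beta = pe$estimate,
               lo = pe$ci[1], hi = pe$ci[2], W = pe$W, B = pe$B,
               df = pe$df)
  })
  coef_tab <- do.call(rbind, coefs)
  rownames(coef_tab) <- NULL
  r2adj <- vapply(per, function(x)
    1 - (1 - x$r2) * (n - 1) / (n - p - 1), numeric(1))
  degenerate <- any(r2adj >= 1 - 1e-12)
  if (degenerate) {
    adj <- structure(list(estimate = 100, ci = c(lo = 100, hi = 100),
                          df = df_com, m = length(tabs),
                          degenerate = TRUE),
                     class = "pooled_estimate")
  } else {
    zr <- atanh(sqrt(pmax(r2adj, 0)))
    pe <- rubin_pool(zr, rep(1 / (n - 3), length(zr)), df_com = n - 3)
    adj <- pe
    adj$estimate <- 100 * tanh(pe$estimate)^2
    adj$ci <- c(lo = 100 * tanh(max(0, pe$ci[1]))^2,
                hi = 100 * tanh(pe$ci[2])^2)
    names(adj$ci) <- c("lo", "hi")
    adj$degenerate <- FALSE
  }
  list(coef = coef_tab, adj_r2 = adj,
       aic = mean(vapply(per, `[[`, numeric(1), "aic")),
       bic = mean(vapply(per, `[[`, numeric(1), "bic")),
       n = n, p = p)
}

#' CI-driven stepwise backward elimination
#'
#' Starting from the candidate set, repeatedly removes, among predictors
#' whose pooled 95\% CI includes zero, the one with smallest absolute
#' pooled standardized beta (ties: wider CI, then lexicographic name),
#' refitting after each removal and recording adjusted R^2. When no
#' zero-including CI remains, removal continues only while dropping the
#' weakest remaining predictor still increases pooled adjusted R^2. An
#' empty final model is a legal outcome.
#'
#' @param stack An `episode_stack`.
#' @param candidates Character vector of candidate predictor columns.
#' @param outcome Outcome column.
#' @param covariates Optional covariate data.frame (see
#'   \code{\link{fit_standardized_model}}).
#' @param label Cluster label attached to the report.
#' @return Object of class `model_report`: list with `label`,
#'   `predictors` (final coefficient table), `adj_r2`, `aic`, `bic`,
#'   `trace` (removed predictor, adjusted R^2 after removal), `n`.
#' @export
stepwise_backward <- function(stack, candidates, outcome = "phq8_sum",
                              covariates = NULL, label = "model") {
  if (!length(candidates))
    return(structure(list(label = label, predictors = NULL,
                          adj_r2 = fit_standardized_model(stack,
                            character(0), outcome)$adj_r2,
                          aic = NA_real_, bic = NA_real_,
                          trace = data.frame(removed = character(0),
                                             adj_r2 = numeric(0)),
                          n = attr(stack, "n") %||% nrow(stack[[1]])),
                     class = "model_report"))
  preds <- candidates
  trace <- data.frame(removed = character(0), adj_r2 = numeric(0))
  fit <- fit_standardized_model(stack, preds, outcome, covariates)
  repeat {
    ct <- fit$coef[fit$coef$predictor %in% preds, , drop = FALSE]
    inc0 <- ct$lo <= 0 & ct$hi >= 0
    if (any(inc0)) {
      cand <- ct[inc0, , drop = FALSE]
      o <- order(abs(cand$beta), -(cand$hi - cand$lo), cand$predictor)
      victim <- cand$predictor[o[1]]
    } else {
      # all CIs exclude zero: continue only if removal improves adj R^2
      if (!nrow(ct)) break
      o <- order(abs(ct$beta), -(ct$hi - ct$lo), ct$predictor)
      victim <- ct$predictor[o[1]]
      trial <- fit_standardized_model(stack, setdiff(preds, victim),
                                      outcome, covariates)
      if (trial$adj_r2$estimate <= fit$adj_r2$estimate) break
      preds <- setdiff(preds, victim)
      fit <- trial
      trace <- rbind(trace, data.frame(removed = victim,
                                       adj_r2 = fit$adj_r2$estimate))
      next
    }
    preds <- setdiff(preds, victim)
    fit <- fit_standardized_model(stack, preds, outcome, covariates)
    trace <- rbind(trace, data.frame(removed = victim,
                                     adj_r2 = fit$adj_r2$estimate))
    if (!length(preds)) break
  }
  structure(list(label = label, predictors = fit$coef,
                 adj_r2 = fit$adj_r2, aic = fit$aic, bic = fit$bic,
                 trace = trace, n = fit$n),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("[%s] adj R2 = %.2f%% (%.2f to %.2f), AIC %.1f, BIC %.1f\n",
              x$label, x$adj_r2$estimate, x$adj_r2$ci[1], x$adj_r2$ci[2],
              x$aic, x$bic))
  if (!is.null(x$predictors) && nrow(x$predictors)) {
    for (i in seq_len(nrow(x$predictors)))
      cat(sprintf("  %-28s beta %+.3f (%.3f to %.3f)\n",
                  x$predictors$predictor[i], x$predictors$beta[i],
                  x$predictors$lo[i], x$predictors$hi[i]))
  } else cat("  (empty model)\n")
  invisible(x)
}

#' Cluster-wise, combined, and sensitivity model suite
#'
#' Runs the full regression program: stepwise models per feature cluster
#' (EMA, app, call, location, screen) on the screened candidates; a
#' sensing-combined model whose candidate pool is the union of the final
#' predictors of the four sensing-cluster models (set
#' `sensing_pool = "screened"` for the union of all screened sensing
#' candidates instead); a combined EMA + sensing model pooling the EMA
#' and sensing-cluster survivors; adjusted-R^2 differences between
#' combined and stand-alone models; and, when `covariates` are given,
#' age/gender sensitivity refits of each final model.
#'
#' @param stack An `episode_stack`.
#' @param screen Result of \code{\link{screen_candidates}}.
#' @param outcome Outcome column.
#' @param covariates Optional data.frame of participant covariates
#'   (aligned to the episode tables' row order), e.g. age and gender.
#' @param sensing_pool "survivors" (default) or "screened".
#' @return List of `model_report`s (`EMA`, `app`, `call`, `location`,
#'   `screen`, `sensing_combined`, `ema_sensing`), `delta_adj_r2`, and
#'   `sensitivity` (refits with covariates appended), plus the screening
#'   table.
#' @export
run_model_suite <- function(stack, screen, outcome = "phq8_sum",
                            covariates = NULL,
                            sensing_pool = c("survivors", "screened")) {
  sensing_pool <- match.arg(sensing_pool)
  clusters <- c("EMA", "app", "call", "location", "screen")
  reports <- list()
  for (cl in clusters) {
    cand <- screen$feature[screen$candidate & screen$cluster == cl]
    reports[[cl]] <- stepwise_backward(stack, cand, outcome, label = cl)
  }
  sens_clusters <- setdiff(clusters, "EMA")
  surv <- unlist(lapply(sens_clusters, function(cl) {
    p <- reports[[cl]]$predictors
    if (is.null(p)) character(0) else p$predictor
  }))
  sens_cand <- if (sensing_pool == "survivors") surv else
    screen$feature[screen$candidate & screen$cluster != "EMA"]
  reports$sensing_combined <- stepwise_backward(
    stack, unique(sens_cand), outcome, label = "sensing_combined")
  ema_surv <- if (is.null(reports$EMA$predictors)) character(0) else
    reports$EMA$predictors$predictor
  reports$ema_sensing <- stepwise_backward(
    stack, unique(c(ema_surv, sens_cand)), outcome,
    label = "ema_sensing")
  delta <- list(
    sensing_vs_ema = if (is.null(reports$sensing_combined$predictors))
      NA_real_ else reports$sensing_combined$adj_r2$estimate -
        reports$EMA$adj_r2$estimate,
    combined_vs_ema = reports$ema_sensing$adj_r2$estimate -
      reports$EMA$adj_r2$estimate,
    combined_vs_sensing = if (is.null(reports$sensing_combined$predictors))
      NA_real_ else reports$ema_sensing$adj_r2$estimate -
        reports$sensing_combined$adj_r2$estimate)
  sensitivity <- NULL
  if (!is.null(covariates)) {
    sensitivity <- lapply(reports, function(rep) {
      preds <- if (is.null(rep$predictors)) character(0) else
        rep$predictors$predictor
      if (!length(preds)) return(NULL)
      fit_standardized_model(stack, preds, outcome,
                             covariates = covariates)
    })
  }
  list(reports = reports, delta_adj_r2 = delta,
       sensitivity = sensitivity, screen = screen)
}

#' Write the inference results to delimited text and JSON
#'
#' Writes `correlations.csv` (feature, cluster, r, lo, hi, candidate),
#' `models.csv` (one row per retained predictor per model with pooled
#' beta, CI, adjusted R-squared, AIC/BIC), and `results.json` (all model
#' reports with their elimination traces and adjusted-R-squared deltas).
#'
#' @param suite Result of \code{\link{run_model_suite}}.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_inference_results <- function(suite, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(suite$screen, file.path(dir, "correlations.csv"),
            row.names = FALSE)
  rows <- list()
  for (rep in suite$reports) {
    if (is.null(rep$predictors) || !nrow(rep$predictors)) next
    rows[[length(rows) + 1L]] <- data.frame(
      model = rep$label, predictor = rep$predictors$predictor,
      beta = rep$predictors$beta, lo = rep$predictors$lo,
      hi = rep$predictors$hi, adj_r2 = rep$adj_r2$estimate,
      adj_r2_lo = unname(rep$adj_r2$ci[1]),
      adj_r2_hi = unname(rep$adj_r2$ci[2]),
      aic = rep$aic, bic = rep$bic)
  }
  write.csv(do.call(rbind, rows), file.path(dir, "models.csv"),
            row.names = FALSE)
  to_json <- lapply(suite$reports, function(rep) list(
    label = rep$label,
    predictors = rep$predictors,
    adj_r2 = list(estimate = rep$adj_r2$estimate,
                  lo = unname(rep$adj_r2$ci[1]),
                  hi = unname(rep$adj_r2$ci[2])),
    aic = rep$aic, bic = rep$bic, trace = rep$trace, n = rep$n))
  jsonlite::write_json(list(models = to_json,
                            delta_adj_r2 = suite$delta_adj_r2),
                       file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
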