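# Rubin pooling, pooled correlations, standardized models, stepwise.

test_that("rubin pooling matches hand computations and the oracle", {
  # all estimates equal -> B = 0, T = u, df = nu_com (nu_com+1)/(nu_com+3)
  p <- rubin_pool(rep(0.3, 4), rep(0.01, 4), df_com = 50)
  expect_equal(p$B, 0)
  expect_equal(p$T, 0.01)
  expect_equal(p$df, 50 * 51 / 53)
  # q = (0, 1), u = (1, 1)
  p2 <- rubin_pool(c(0, 1), c(1, 1), df_com = 100)
  expect_equal(p2$estimate, 0.5)
  expect_equal(p2$B, 0.5)
  expect_equal(p2$T, 1 + 1.5 * 0.5)
  # T >= W always; oracle equivalence on random inputs
  set.seed(77)
  for (i in 1:200) {
    m <- sample(2:8, 1)
    q <- rnorm(m); u <- runif(m, 0.01, 2)
    nu <- sample(5:200, 1)
    got <- rubin_pool(q, u, df_com = nu)
    want <- oracle_rubin(q, u, nu)
    expect_equal(got$estimate, want$qbar, tolerance = 1e-12)
    expect_equal(got$T, want$T, tolerance = 1e-12)
    expect_equal(got$df, want$df, tolerance = 1e-9)
    expect_equal(unname(got$ci), want$ci, tolerance = 1e-9)
    expect_gte(got$T, got$W)
  }
  expect_error(rubin_pool(c(1, 2), c(0.1, -0.1), 10), ">= 0")
  # m = 1 passes through
  p1 <- rubin_pool(0.2, 0.04, df_com = 30)
  expect_equal(p1$estimate, 0.2)
  expect_equal(p1$df, 30)
})

test_that("pooled correlation reproduces the 4-point hand example", {
  tab <- data.frame(x = c(0, 1, 2, 3), phq8_sum = c(0, 1, 0, 1))
  st <- as_stack(tab, tab, tab)
  p <- pooled_correlation(st, "x")
  expect_equal(p$estimate, cor(tab$x, tab$phq8_sum), tolerance = 1e-12)
  expect_equal(p$estimate, 0.4472, tolerance = 1e-4)
  expect_equal(p$B, 0)
  # B = 0 means the CI equals the single-dataset Fisher CI (BR df)
  z <- atanh(p$estimate)
  half <- qt(0.975, 1 * 2 / 4) * sqrt(1)  # df = nu(nu+1)/(nu+3), nu = 1
  expect_equal(unname(p$ci),
               tanh(z + c(-1, 1) * half), tolerance = 1e-9)
  # degenerate and symmetric cases
  tab2 <- data.frame(x = 1:6, phq8_sum = 1:6)
  pd <- pooled_correlation(as_stack(tab2, tab2), "x")
  expect_true(pd$degenerate)
  expect_equal(pd$estimate, 1)
  tab3 <- data.frame(x = c(4, 1, 3, 8, 2), phq8_sum = c(2, 0, 9, 1, 5))
  pxy <- pooled_correlation(as_stack(tab3), "x", "phq8_sum")
  tab3r <- data.frame(x = tab3$phq8_sum, phq8_sum = tab3$x)
  pyx <- pooled_correlation(as_stack(tab3r), "x", "phq8_sum")
  expect_equal(pxy$estimate, pyx$estimate, tolerance = 1e-12)
  expect_error(pooled_correlation(as_stack(
    data.frame(x = rep(1, 5), phq8_sum = 1:5)), "x"), "zero variance")
})

test_that("candidate screening keeps CIs excluding zero, by cluster", {
  set.seed(5)
  n <- 200
  z <- rnorm(n)
  tab <- data.frame(phq8_sum = z + rnorm(n, sd = 0.5),
                    mean_ema_valence = -0.6 * z + rnorm(n, sd = 0.8),
                    mean_screen_duration_mean = 0.5 * z + rnorm(n),
                    mean_app_count = rnorm(n),
                    sd_app_freq_entropy = rep(2, n))  # zero variance
  sc <- screen_candidates(as_stack(tab))
  expect_true(sc$candidate[sc$feature == "mean_ema_valence"])
  expect_true(sc$candidate[sc$feature == "mean_screen_duration_mean"])
  expect_false(sc$candidate[sc$feature == "mean_app_count"])
  expect_false(sc$candidate[sc$feature == "sd_app_freq_entropy"])
  expect_true(is.na(sc$r[sc$feature == "sd_app_freq_entropy"]))
  expect_equal(sc$cluster[sc$feature == "mean_ema_valence"], "EMA")
  expect_equal(sc$cluster[sc$feature == "mean_screen_duration_mean"],
               "screen")
})

test_that("standardized single-predictor beta equals the correlation", {
  set.seed(8)
  tab <- data.frame(x = rnorm(40))
  tab$phq8_sum <- 0.5 * tab$x + rnorm(40)
  f <- fit_standardized_model(as_stack(tab), "x")
  expect_equal(f$coef$beta, cor(tab$x, tab$phq8_sum), tolerance = 1e-9)
})

test_that("adjusted R2 matches the closed form and summary.lm", {
  # R2 = 0.5, n = 11, p = 2 -> 37.5%
  expect_equal(1 - (1 - 0.5) * (11 - 1) / (11 - 2 - 1), 0.375)
  set.seed(12)
  for (i in 1:200) {
    n <- sample(15:40, 1); p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- X %*% runif(p, 0.5, 1) + rnorm(n)
    tab <- data.frame(X, phq8_sum = as.numeric(y))
    preds <- names(tab)[1:p]
    f <- fit_standardized_model(as_stack(tab), preds)
    d <- as.data.frame(scale(tab))
    want <- summary(lm(phq8_sum ~ ., data = d))$adj.r.squared
    if (want > 0)  # pooled scale is defined for non-negative adj R2
      expect_equal(f$adj_r2$estimate, 100 * want, tolerance = 1e-6)
  }
})

test_that("pooled quantities reduce exactly to single-dataset values", {
  s <- sim_day_with_outcome(80, effect_map = list(
    ema_valence = -0.5, screen_duration_mean = 0.4, app_count = 0),
    seed = 19)
  st <- impute_pmm(s$day, imputation_spec(m = 4, iterations = 2,
                                          seed = 3))
  ag <- aggregate_stack(st)
  one <- ag[[1]]
  # correlations
  p <- pooled_correlation(ag, "mean_ema_valence")
  expect_equal(p$B, 0)
  expect_equal(p$estimate, cor(one$mean_ema_valence, one$phq8_sum),
               tolerance = 1e-12)
  # betas and adjusted R2
  f <- fit_standardized_model(ag, c("mean_ema_valence",
                                    "mean_screen_duration_mean"))
  d <- data.frame(y = scale(one$phq8_sum)[, 1],
                  a = scale(one$mean_ema_valence)[, 1],
                  b = scale(one$mean_screen_duration_mean)[, 1])
  sfit <- summary(lm(y ~ a + b, data = d))
  expect_equal(sort(f$coef$beta), sort(unname(coef(sfit)[2:3, 1])),
               tolerance = 1e-9)
  expect_equal(f$adj_r2$estimate, 100 * sfit$adj.r.squared,
               tolerance = 1e-9)
  expect_true(all(f$coef$B == 0))
})

test_that("stepwise keeps strong orthogonal predictors, drops noise", {
  set.seed(33)
  n <- 300
  x1 <- rnorm(n); x2 <- rnorm(n)
  tab <- data.frame(x1 = x1, x2 = x2, x3 = rnorm(n), x4 = rnorm(n),
                    phq8_sum = 0.5 * x1 + 0.5 * x2 + rnorm(n))
  st <- as_stack(tab)
  mr <- stepwise_backward(st, c("x1", "x2", "x3", "x4"))
  expect_setequal(mr$predictors$predictor, c("x1", "x2"))
  # every retained CI excludes zero; trace shrinks the model one at a time
  expect_true(all(mr$predictors$lo > 0 | mr$predictors$hi < 0))
  expect_equal(nrow(mr$trace), 2)
  # pure-noise candidates lead to an empty (or noise-free) model
  tabn <- data.frame(n1 = rnorm(150), n2 = rnorm(150), n3 = rnorm(150),
                     phq8_sum = rnorm(150))
  mrn <- stepwise_backward(as_stack(tabn), c("n1", "n2", "n3"))
  expect_lte(NROW(mrn$predictors), 1)
})

test_that("the model suite nests EMA and sensing models coherently", {
  s <- sim_day_with_outcome(250, effect_map = list(
    ema_valence = -0.5, ema_social_quality = -0.4, ema_stress = 0,
    screen_duration_mean = 0.4, app_count = 0,
    call_incoming_count = 0.3), seed = 41)
  ag <- as_stack(aggregate_to_episode(s$day))
  sc <- screen_candidates(ag, features = grep("^mean_",
                                              names(ag[[1]]),
                                              value = TRUE))
  suite <- run_model_suite(ag, sc,
                           covariates = data.frame(
                             age = s$participants$age,
                             gender = s$participants$gender))
  expect_named(suite$reports,
               c("EMA", "app", "call", "location", "screen",
                 "sensing_combined", "ema_sensing"))
  # combined model explains at least as much as the stand-alone models
  expect_gte(suite$reports$ema_sensing$adj_r2$estimate + 1e-9,
             max(suite$reports$EMA$adj_r2$estimate,
                 suite$reports$sensing_combined$adj_r2$estimate))
  expect_equal(suite$delta_adj_r2$combined_vs_ema,
               suite$reports$ema_sensing$adj_r2$estimate -
                 suite$reports$EMA$adj_r2$estimate)
  # null age/gender covariates keep zero-including CIs in sensitivity
  sens <- suite$sensitivity$ema_sensing
  ag_rows <- sens$coef[sens$coef$predictor %in% c("age", "gender"), ]
  expect_true(all(ag_rows$lo <= 0 & ag_rows$hi >= 0))
})

test_that("pipeline writers emit the expected text artifacts", {
  s <- sim_day_with_outcome(60, effect_map = list(
    ema_valence = -0.5, screen_duration_mean = 0.4), seed = 71)
  ag <- as_stack(aggregate_to_episode(s$day))
  sc <- screen_candidates(ag)
  suite <- run_model_suite(ag, sc)
  dir <- tempfile("results")
  on.exit(unlink(dir, recursive = TRUE))
  write_inference_results(suite, dir)
  corr <- read.csv(file.path(dir, "correlations.csv"))
  expect_true(all(c("feature", "r", "lo", "hi") %in% names(corr)))
  models <- read.csv(file.path(dir, "models.csv"))
  expect_true(all(c("model", "predictor", "beta", "adj_r2") %in%
                    names(models)))
  res <- jsonlite::read_json(file.path(dir, "results.json"))
  expect_true("models" %in% names(res))
})
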