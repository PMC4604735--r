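sim_logit_df <- function(n, beta0, beta, seed) {
  set.seed(seed)
  lact <- rlnorm(n, log(2), 0.6)
  eta <- beta0 + beta * lact
  data.frame(patient_id = paste0("s", 1:n), lactate = lact,
             icu_outcome = ifelse(runif(n) < plogis(eta), "died", "survived"),
             stringsAsFactors = FALSE)
}

test_that("the fit recovers a known slope and satisfies the AIC identity", {
  df <- sim_logit_df(5000, -1, 0.6, seed = 301)
  fit <- fit_logistic(df, "lactate")
  expect_lt(abs(fit$coefficients[["lactate"]] - 0.6), 0.1)
  k <- length(fit$coefficients)
  expect_equal(fit$aic, 2 * k - 2 * fit$log_likelihood, tolerance = 1e-10)
  # log-likelihood against a first-principles Bernoulli computation
  p_hat <- plogis(fit$linear_predictor)
  y <- df$icu_outcome == "died"
  expect_equal(fit$log_likelihood,
               sum(log(ifelse(y, p_hat, 1 - p_hat))), tolerance = 1e-8)
  # odds ratios and Wald CIs are exact transforms of the coefficients
  expect_equal(fit$odds_ratio, exp(fit$coefficients), tolerance = 1e-12)
  expect_equal(fit$or_ci_low,
               exp(fit$coefficients - qnorm(0.975) * fit$se),
               tolerance = 1e-12)
  expect_true(all(fit$or_ci_low <= fit$odds_ratio &
                    fit$odds_ratio <= fit$or_ci_high))
})

test_that("an intercept-only fit reproduces the marginal log-odds", {
  df <- data.frame(patient_id = paste0("q", 1:100),
                   icu_outcome = rep(c("died", "survived"), c(30, 70)))
  fit <- fit_logistic(df, character(0))
  expect_equal(fit$coefficients[["(Intercept)"]], qlogis(0.3),
               tolerance = 1e-6)
})

test_that("degenerate designs are rejected with informative errors", {
  df <- sim_logit_df(100, 0, 0.5, seed = 302)
  df$flat <- 1
  expect_error(fit_logistic(df, "flat"), "rank-deficient|separation")
  df$sep <- ifelse(df$icu_outcome == "died", 10, 0)
  err <- expect_error(fit_logistic(df, c("lactate", "sep")))
  expect_match(conditionMessage(err), "separation")
  expect_match(conditionMessage(err), "sep")
  expect_error(fit_logistic(df[1:5, ], "lactate"), "10 complete cases")
})

test_that("parameter recovery stays within 3 SE in repeated simulation", {
  inside <- vapply(1:60, function(r) {
    df <- sim_logit_df(400, -1, 0.6, seed = 5000 + r)
    fit <- fit_logistic(df, "lactate")
    abs(fit$coefficients[["lactate"]] - 0.6) <= 3 * fit$se[["lactate"]]
  }, TRUE)
  expect_gte(mean(inside), 0.95)
})

test_that("stepwise matches exhaustive best-subset AIC on few candidates", {
  set.seed(303)
  n <- 250
  df <- data.frame(patient_id = paste0("e", 1:n),
                   x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))
  eta <- -0.5 + 1.2 * df$x1 + 0.8 * df$x3
  df$icu_outcome <- ifelse(runif(n) < plogis(eta), "died", "survived")
  cands <- c("x1", "x2", "x3", "x4")
  step_fit <- stepwise_aic(df, cands)
  subsets <- unlist(lapply(0:4, function(k)
    combn(cands, k, simplify = FALSE)), recursive = FALSE)
  aics <- vapply(subsets, function(s) fit_logistic(df, s)$aic, 0)
  best <- subsets[[which.min(aics)]]
  expect_setequal(step_fit$predictors, best)
})

test_that("stepwise returns the null model when nothing improves", {
  set.seed(304)
  n <- 60
  df <- data.frame(patient_id = paste0("n", 1:n), x1 = rnorm(n))
  df$icu_outcome <- rep(c("died", "survived"), c(20, 40))
  fit <- stepwise_aic(df, "x1")
  null_aic <- fit_logistic(df, character(0))$aic
  alt_aic <- fit_logistic(df, "x1")$aic
  if (alt_aic >= null_aic) {
    expect_length(fit$predictors, 0)
  } else {
    expect_equal(fit$predictors, "x1")
  }
})

test_that("stepwise selection is invariant to record order", {
  set.seed(305)
  n <- 200
  df <- data.frame(patient_id = paste0("o", 1:n), x1 = rnorm(n),
                   x2 = rnorm(n), x3 = rnorm(n))
  df$icu_outcome <- ifelse(runif(n) < plogis(-0.5 + df$x1), "died", "survived")
  f1 <- stepwise_aic(df, c("x1", "x2", "x3"))
  f2 <- stepwise_aic(df[sample(n), ], c("x1", "x2", "x3"))
  expect_identical(f1$predictors, f2$predictors)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-10)
})

test_that("the likelihood-ratio comparison matches deviance arithmetic", {
  df <- sim_logit_df(500, -1, 0.6, seed = 306)
  df$noise <- rnorm(500)
  nested <- fit_logistic(df, "lactate")
  full <- fit_logistic(df, c("lactate", "noise"))
  res <- lrt_anova(nested, full)
  expect_equal(res$deviance_diff,
               2 * (full$log_likelihood - nested$log_likelihood))
  expect_equal(res$df, 1)
  same <- lrt_anova(nested, nested)
  expect_equal(same$deviance_diff, 0)
  expect_equal(same$p, 1)
  other <- fit_logistic(df, "noise")
  expect_error(lrt_anova(other, nested), "nested")
})

test_that("null likelihood-ratio p-values are uniform", {
  set.seed(307)
  ps <- vapply(1:400, function(r) {
    n <- 150
    df <- data.frame(patient_id = paste0("u", 1:n), x = rnorm(n),
                     z = rnorm(n))
    df$icu_outcome <- ifelse(runif(n) < plogis(-0.7 + 0.5 * df$x),
                             "died", "survived")
    if (length(unique(df$icu_outcome)) < 2) return(NA_real_)
    lrt_anova(fit_logistic(df, "x"), fit_logistic(df, c("x", "z")))$p
  }, 0)
  ps <- ps[!is.na(ps)]
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("phi matches its closed formula and flags degenerate margins", {
  tab <- rbind(c(20, 5), c(6, 19))
  by_hand <- (20 * 19 - 5 * 6) / sqrt(25 * 25 * 26 * 24)
  expect_equal(phi_coefficient(tab), by_hand)
  expect_equal(round(by_hand, 2), 0.56)
  expect_warning(res <- phi_coefficient(rbind(c(0, 0), c(3, 4))),
                 "degenerate")
  expect_true(is.na(res))
})

test_that("cut-point transport reproduces perfect and null association", {
  set.seed(308)
  n <- 120
  mk <- function(seed, beta) {
    set.seed(seed)
    x <- rnorm(n)
    data.frame(patient_id = paste0("c", seed, "_", 1:n), lactate = exp(x),
               icu_outcome = ifelse(runif(n) < plogis(-0.5 + beta * x),
                                    "died", "survived"))
  }
  src <- mk(1, 2); tgt <- mk(2, 2)
  fit <- fit_logistic(src, "lactate")
  cv <- transport_cut_point(fit, src, tgt)
  expect_s3_class(cv, "crossval_result")
  expect_true(cv$phi > 0.3 && cv$phi <= 1)
  expect_lt(cv$p, 0.01)
  # outcome shuffled in the target: association should vanish
  tgt_null <- tgt
  set.seed(42)
  tgt_null$icu_outcome <- sample(tgt_null$icu_outcome)
  cv0 <- transport_cut_point(fit, src, tgt_null)
  expect_lt(abs(cv0$phi), 0.15)
  expect_gt(cv0$p, 0.05)
})
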