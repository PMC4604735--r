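# Binary logistic regression against ICU mortality, deterministic stepwise
# AIC selection, likelihood-ratio (ANOVA) comparison, and cross-cohort
# cut-point transport with chi-squared goodness-of-fit and phi.

#' Fit a binary logistic regression
#'
#' Maximum-likelihood logistic fit of ICU death on the given predictors over
#' complete cases, with Wald z tests, odds ratios and symmetric Wald 95%
#' confidence intervals (`exp(coef +/- 1.96 SE)`). Perfect separation and
#' rank deficiency are detected and raised as errors naming the culprit
#' predictor.
#'
#' @param x A `cohort` or record data.frame.
#' @param predictors Character vector of numeric predictor fields.
#' @param outcome Outcome field (default `"icu_outcome"`, died = 1).
#' @return Object of class `logit_fit`: `terms`, `coefficients` (incl.
#'   intercept), `se`, `z`, `p`, `odds_ratio`, `or_ci_low`, `or_ci_high`,
#'   `log_likelihood`, `aic`, `n_used`, `linear_predictor` (named by patient
#'   id), `predictors`, `outcome`.
#' @export
fit_logistic <- function(x, predictors, outcome = "icu_outcome") {
  df <- as.data.frame(x)
  missing_cols <- setdiff(c(predictors, outcome), names(df))
  if (length(missing_cols))
    abort_validation(paste("unknown field(s):",
                           paste(missing_cols, collapse = ", ")))
  y <- as_binary_outcome(df[[outcome]])
  keep <- !is.na(y)
  for (p in predictors) keep <- keep & !is.na(df[[p]])
  d <- df[keep, , drop = FALSE]
  y <- y[keep]
  if (nrow(d) < 10L)
    abort_validation("fit_logistic needs at least 10 complete cases")
  if (length(unique(y)) < 2L)
    abort_validation("outcome has a single class among complete cases")
  mf <- data.frame(.y = as.integer(y), d[, predictors, drop = FALSE])
  form <- stats::as.formula(paste(
    ".y ~", if (length(predictors)) paste(predictors, collapse = " + ")
            else "1"))
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = mf,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  if (anyNA(co))
    abort_validation(paste("rank-deficient design; aliased term(s):",
                           paste(names(co)[is.na(co)], collapse = ", ")))
  # separation: diverging scale-adjusted slopes, a vanishing deviance, or
  # glm's own extreme-probability warning
  slope_scale <- if (length(predictors))
    vapply(predictors, function(p) stats::sd(d[[p]]), 0) else numeric(0)
  scaled <- abs(co[-1][predictors] * slope_scale)
  if (sep_warned || any(scaled > 12) || fit$deviance < 1e-6) {
    culprit <- if (length(scaled)) names(which.max(scaled)) else "intercept"
    abort_validation(paste0("(quasi-)perfect separation detected; ",
                            "diverging coefficient for '", culprit, "'"))
  }
  sm <- summary(fit)$coefficients
  term_names <- rownames(sm)
  ll <- as.numeric(stats::logLik(fit))
  zq <- stats::qnorm(0.975)
  nm <- function(col) stats::setNames(as.numeric(sm[, col]), term_names)
  res <- structure(list(
    terms = term_names,
    coefficients = nm(1), se = nm(2), z = nm(3), p = nm(4),
    odds_ratio = exp(nm(1)),
    or_ci_low = exp(nm(1) - zq * nm(2)),
    or_ci_high = exp(nm(1) + zq * nm(2)),
    log_likelihood = ll,
    aic = stats::AIC(fit),
    n_used = nrow(d),
    linear_predictor = stats::setNames(
      as.numeric(fit$linear.predictors),
      if ("patient_id" %in% names(d)) d$patient_id else rownames(d)),
    predictors = predictors, outcome = outcome),
    class = "logit_fit")
  res
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("<logit_fit> %s ~ %s\n", x$outcome,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "1"))
  tab <- data.frame(coef = x$coefficients, se = x$se,
                    OR = x$odds_ratio, ci_low = x$or_ci_low,
                    ci_high = x$or_ci_high, p = x$p)
  print(round(tab, 4))
  cat(sprintf("n = %d, logLik = %.3f, AIC = %.3f\n",
              x$n_used, x$log_likelihood, x$aic))
  invisible(x)
}

#' Model summary as a data.frame
#' @param fit A `logit_fit`.
#' @return Data.frame with term, coefficient, SE, OR, CI and p per row.
#' @export
logit_summary_table <- function(fit) {
  data.frame(term = fit$terms, coefficient = unname(fit$coefficients),
             se = unname(fit$se), odds_ratio = unname(fit$odds_ratio),
             or_ci_low = unname(fit$or_ci_low),
             or_ci_high = unname(fit$or_ci_high),
             p = unname(fit$p), stringsAsFactors = FALSE)
}

#' Stepwise AIC model selection
#'
#' Deterministic greedy bidirectional search from the intercept-only model:
#' at each step every single-predictor addition and removal is scored, the
#' move with the lowest AIC is taken if it strictly improves on the current
#' model, and ties are broken toward fewer parameters and then toward the
#' declared candidate order. The record set is fixed to complete cases over
#' all candidates before the search, so all models compared are fitted to
#' the same data and their AICs are comparable. The result is invariant to
#' record order.
#'
#' @param x A `cohort` or record data.frame.
#' @param candidates Character vector of candidate predictors (scan order is
#'   the declared order).
#' @param outcome Outcome field.
#' @return The selected model as a `logit_fit` (with attribute `path`, the
#'   sequence of moves taken).
#' @export
stepwise_aic <- function(x, candidates, outcome = "icu_outcome") {
  if (!length(candidates)) abort_validation("candidates must be non-empty")
  df <- as.data.frame(x)
  missing_cols <- setdiff(c(candidates, outcome), names(df))
  if (length(missing_cols))
    abort_validation(paste("unknown field(s):",
                           paste(missing_cols, collapse = ", ")))
  keep <- rep(TRUE, nrow(df))
  y <- as_binary_outcome(df[[outcome]])
  keep <- keep & !is.na(y)
  for (p in candidates) keep <- keep & !is.na(df[[p]])
  d <- df[keep, , drop = FALSE]
  current <- character(0)
  current_fit <- fit_logistic(d, current, outcome)
  path <- character(0)
  repeat {
    moves <- list()
    for (p in setdiff(candidates, current))
      moves[[length(moves) + 1L]] <- list(op = "+", term = p,
                                          set = c(current, p))
    for (p in current)
      moves[[length(moves) + 1L]] <- list(op = "-", term = p,
                                          set = setdiff(current, p))
    if (!length(moves)) break
    aics <- vapply(moves, function(mv) {
      fit <- try(fit_logistic(d, mv$set, outcome), silent = TRUE)
      if (inherits(fit, "try-error")) Inf else fit$aic
    }, 0)
    sizes <- vapply(moves, function(mv) length(mv$set), 0L)
    ord <- order(aics, sizes)        # ties -> fewer parameters, then scan order
    best <- ord[1]
    if (aics[best] >= current_fit$aic - 1e-10) break
    current <- moves[[best]]$set
    current_fit <- fit_logistic(d, current, outcome)
    path <- c(path, paste0(moves[[best]]$op, moves[[best]]$term))
  }
  # refit with predictors in declared candidate order for a stable report
  current_fit <- fit_logistic(d, candidates[candidates %in% current], outcome)
  attr(current_fit, "path") <- path
  current_fit
}

#' Likelihood-ratio (ANOVA) comparison of nested logistic models
#'
#' Chi-squared test on twice the log-likelihood difference with degrees of
#' freedom equal to the parameter-count difference. The models must be
#' nested and fitted to the same records.
#'
#' @param nested,full `logit_fit` objects with `nested$predictors` a subset
#'   of `full$predictors`.
#' @return List with `deviance_diff`, `df`, `p`.
#' @export
lrt_anova <- function(nested, full) {
  stopifnot(inherits(nested, "logit_fit"), inherits(full, "logit_fit"))
  if (!all(nested$predictors %in% full$predictors))
    abort_validation("models are not nested")
  if (nested$n_used != full$n_used)
    abort_validation("models were fitted to different record sets")
  dd <- 2 * (full$log_likelihood - nested$log_likelihood)
  df <- length(full$predictors) - length(nested$predictors)
  p <- if (df == 0L) 1 else stats::pchisq(max(dd, 0), df, lower.tail = FALSE)
  list(deviance_diff = dd, df = df, p = p)
}

#' Phi coefficient of a 2x2 table
#'
#' `(ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))` -- the Pearson correlation of
#' the two binary margins. `NA` with a warning when any margin is zero.
#'
#' @param table 2x2 count matrix.
#' @return Numeric in `[-1, 1]`, or `NA`.
#' @export
phi_coefficient <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  denom <- sqrt(prod(c(a + b, c + d, a + c, b + d)))
  if (denom == 0) {
    warning("degenerate 2x2 margin: phi undefined")
    return(NA_real_)
  }
  (a * d - b * c) / denom
}

#' Transport a model's cut point to another cohort
#'
#' Applies a model fitted on a source cohort to a target cohort: the
#' Youden-optimal cut point of the source linear predictor's ROC is used to
#' predict death in the target (predicted death when the linear predictor
#' exceeds the cut), and the predicted-by-observed 2x2 table is assessed by
#' chi-squared with Yates correction and the phi coefficient.
#'
#' @param model A `logit_fit` fitted on the source cohort.
#' @param source_cohort,target_cohort Cohorts containing the model's
#'   predictors; complete cases are used in each.
#' @return Object of class `crossval_result`: `source`, `target`,
#'   `cut_point`, `table` (2x2 predicted x observed), `chi2`, `p`, `phi`,
#'   `accuracy`.
#' @export
transport_cut_point <- function(model, source_cohort, target_cohort) {
  stopifnot(inherits(model, "logit_fit"))
  lp <- function(ch) {
    df <- as.data.frame(ch)
    keep <- rep(TRUE, nrow(df))
    for (p in model$predictors) keep <- keep & !is.na(df[[p]])
    d <- df[keep, , drop = FALSE]
    eta <- rep(model$coefficients[["(Intercept)"]], nrow(d))
    for (p in model$predictors) eta <- eta + model$coefficients[[p]] * d[[p]]
    list(eta = eta, y = as_binary_outcome(d[[model$outcome]]))
  }
  src <- lp(source_cohort)
  roc <- roc_curve(src$eta, src$y, name = "linear_predictor")
  cut <- youden_cut_point(roc)$cut_point
  tgt <- lp(target_cohort)
  pred <- tgt$eta > cut
  tab <- table(predicted = factor(pred, c(TRUE, FALSE)),
               observed = factor(tgt$y, c(TRUE, FALSE)))
  ct <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    list(statistic = NA_real_, p = NA_real_)
  else categorical_test(tab, method = "chi2_yates")
  structure(list(
    source = cohort_label(source_cohort) %||% "source",
    target = cohort_label(target_cohort) %||% "target",
    cut_point = cut, table = unclass(tab),
    chi2 = ct$statistic, p = ct$p,
    phi = phi_coefficient(tab),
    accuracy = mean(pred == tgt$y)),
    class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("<crossval> %s -> %s, cut %.3f\n", x$source, x$target,
              x$cut_point))
  print(x$table)
  cat(sprintf("chi2 = %.3f, p = %s, phi = %.3f, accuracy = %.2f\n",
              x$chi2, format_p(x$p), x$phi, x$accuracy))
  invisible(x)
}
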