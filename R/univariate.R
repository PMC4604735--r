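# Univariate outcome-association battery: Welch t, Mann-Whitney U,
# chi-squared with Yates correction / Fisher exact, and the cohort-table
# driver that emits one row per variable with per-variable complete cases.

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and two-sided p, for continuous variables presented as mean (range).
#'
#' @param x,y Numeric samples (missing values dropped); each needs at least
#'   two values and at least one group must have nonzero variance.
#' @return List with `statistic`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    abort_validation("welch_t needs at least 2 non-missing values per group")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    abort_validation("welch_t is undefined when both groups are constant")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midrank tie handling, for continuous variables
#' presented as median (IQR). The p-value is exact (enumeration over
#' labelings) when both groups have fewer than 8 values and there are no
#' ties; otherwise the normal approximation with continuity correction is
#' used. The reported `U` counts pairs where an `x` exceeds a `y` (ties as
#' one half), so `U + U' = n1 * n2`.
#'
#' @param x,y Numeric samples (missing values dropped, each non-empty).
#' @return List with `U`, `p`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L)
    abort_validation("mann_whitney needs non-empty groups")
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  if (max(c(x, y)) == min(c(x, y)))
    return(list(U = U, p = 1))
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) < 8L && length(y) < 8L && !has_ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = U, p = ht$p.value)
}

#' 2x2 categorical association test
#'
#' Pearson chi-squared with Yates continuity correction, or Fisher's exact
#' test (two-sided probability-mass convention: sum of hypergeometric
#' probabilities at or below the observed table's). With `method = "auto"`,
#' Fisher is substituted whenever any expected cell count is below 5.
#'
#' @param table 2x2 matrix of non-negative integer counts with nonzero
#'   margins (rows: groups; columns: outcome).
#' @param method `"auto"`, `"chi2_yates"` or `"fisher"`.
#' @return List with `method` (the test actually used), `statistic`
#'   (chi-squared statistic, `NA` for Fisher), `p`.
#' @export
categorical_test <- function(table, method = c("auto", "chi2_yates",
                                               "fisher")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    abort_validation("categorical_test needs a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    abort_validation("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    abort_validation("categorical_test needs nonzero margins")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (method == "auto")
    method <- if (any(expected < 5)) "fisher" else "chi2_yates"
  if (method == "fisher") {
    ht <- stats::fisher.test(table)
    list(method = "fisher", statistic = NA_real_, p = ht$p.value)
  } else {
    ht <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
    list(method = "chi2_yates", statistic = unname(ht$statistic),
         p = ht$p.value)
  }
}

#' Default univariate variable plan
#'
#' One row per variable with the summary presentation and test used in
#' cohort characteristic tables: mean (range) with Welch t for roughly
#' symmetric variables, median (IQR) with Mann-Whitney U for right-skewed
#' ones, and n (%) with chi-squared/Fisher for categorical ones (ascites and
#' encephalopathy collapsed to any-vs-none).
#'
#' @return Data.frame with columns `variable`, `kind`, `test`, `positive`
#'   (the level counted for categorical variables).
#' @export
default_variable_plan <- function() {
  rbind(
    data.frame(variable = c("age", "sodium", "potassium", "wcc", "albumin",
                            "platelets"),
               kind = "mean_range", test = "welch_t", positive = NA),
    data.frame(variable = c("urea", "lactate", "creatinine", "bilirubin",
                            "pt_ratio", "pao2", "pf_ratio"),
               kind = "median_iqr", test = "mann_whitney_u", positive = NA),
    data.frame(variable = c("sex", "alcoholic_aetiology", "ascites",
                            "encephalopathy"),
               kind = "count_percent", test = "categorical_auto",
               positive = c("male", "TRUE", "any", "any"))
  )
}

# Binary indicator for the categorical variables in the plan.
binary_indicator <- function(x, variable, positive) {
  v <- x[[variable]]
  switch(variable,
    sex = v == "male",
    alcoholic_aetiology = as.logical(v),
    ascites = if (identical(positive, "any")) v != "none"
              else v %in% positive,
    encephalopathy = if (identical(positive, "any")) v > 0
                     else v %in% as.numeric(positive),
    as.character(v) %in% positive)
}

#' Univariate association table
#'
#' Runs the configured test for every variable in the plan against ICU
#' outcome, with per-variable complete cases (pairwise deletion), and
#' summaries for survivors and non-survivors.
#'
#' @param x A `cohort`.
#' @param plan A variable plan (see [default_variable_plan()]); variables not
#'   present in the cohort are skipped.
#' @return Data.frame with one row per variable: `variable`,
#'   `summary_survivor`, `summary_death`, `test`, `statistic`, `p`,
#'   `p_formatted`.
#' @export
univariate_table <- function(x, plan = default_variable_plan()) {
  died <- x$icu_outcome == "died"
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    variable <- plan$variable[i]
    if (!variable %in% names(x)) return(NULL)
    kind <- plan$kind[i]
    surv <- as.data.frame(x)[!died, , drop = FALSE]
    dead <- as.data.frame(x)[died, , drop = FALSE]
    if (plan$test[i] %in% c("welch_t", "mann_whitney_u")) {
      a <- surv[[variable]]; b <- dead[[variable]]
      if (sum(!is.na(a)) < 2L || sum(!is.na(b)) < 2L) return(NULL)
      res <- if (plan$test[i] == "welch_t") {
        r <- welch_t(a, b); list(stat = r$statistic, p = r$p)
      } else {
        r <- mann_whitney(a, b); list(stat = r$U, p = r$p)
      }
      s_s <- summarize_field(surv, variable, kind)$formatted
      s_d <- summarize_field(dead, variable, kind)$formatted
      test_used <- plan$test[i]
    } else {
      pos <- binary_indicator(x, variable, plan$positive[i])
      ok <- !is.na(pos)
      if (length(unique(pos[ok])) < 2L || length(unique(died[ok])) < 2L)
        return(NULL)
      tab <- table(factor(pos[ok], c(FALSE, TRUE)),
                   factor(died[ok], c(FALSE, TRUE)))
      res <- categorical_test(t(tab), method = "auto")
      res <- list(stat = res$statistic, p = res$p, used = res$method)
      fmt <- function(idx) sprintf("%d (%.1f%%)", sum(pos[ok & idx]),
                                   100 * sum(pos[ok & idx]) / sum(idx))
      s_s <- fmt(!died); s_d <- fmt(died)
      test_used <- res$used
    }
    data.frame(variable = variable, summary_survivor = s_s,
               summary_death = s_d, test = test_used,
               statistic = res$stat %||% NA_real_, p = res$p,
               p_formatted = format_p(res$p), stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
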