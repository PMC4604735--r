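# Empirical ROC analysis: curves, AUC (dual trapezoid/rank routes), DeLong
# variance from placement values, Youden cut points, paired curve comparison
# and the clinical-usefulness threshold.

# Mann-Whitney kernel placements: for each positive score, the fraction of
# negative scores it beats (ties count one half); and symmetrically for
# negatives. AUC is the mean of either set.
delong_placements <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n            # P(X > Y) + P(X = Y)/2
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Empirical ROC curve
#'
#' Builds the empirical ROC of a score against a binary outcome over all
#' distinct score values. At each threshold `t` a record is predicted
#' positive when its score exceeds `t` (for `higher_is_positive`;
#' `lower_is_positive` reverses the comparison without sign-flipping the
#' data). The AUC is computed both by the trapezoidal rule over the curve
#' and by the midrank Mann-Whitney formula (ties counted one half); the two
#' routes must agree to 1e-12 and the shared value is returned.
#'
#' @param scores Numeric score vector; records with missing scores are
#'   dropped together with their labels.
#' @param labels Binary outcomes: logical, 0/1, or a factor/character with
#'   levels survived/died (died = positive).
#' @param orientation `"higher_is_positive"` (default) or
#'   `"lower_is_positive"`.
#' @param name Score name carried into reports.
#' @return Object of class `roc_result`: `thresholds` (ascending distinct
#'   scores), `sensitivity`, `specificity` at each threshold, `auc`,
#'   `auc_ci95` (DeLong), `n_positive`, `n_negative`, plus the retained
#'   scores for downstream paired tests.
#' @export
roc_curve <- function(scores, labels,
                      orientation = c("higher_is_positive",
                                      "lower_is_positive"),
                      name = "score") {
  orientation <- match.arg(orientation)
  lab <- as_binary_outcome(labels)
  ok <- !is.na(scores) & !is.na(lab)
  s <- as.numeric(scores)[ok]; y <- lab[ok]
  if (sum(y) == 0L || sum(!y) == 0L)
    abort_validation("roc_curve needs at least one positive and one negative")
  eff <- if (orientation == "higher_is_positive") s else -s
  pos <- eff[y]; neg <- eff[!y]
  thr_eff <- sort(unique(eff))
  sens <- vapply(thr_eff, function(t) mean(pos > t), 0)
  spec <- vapply(thr_eff, function(t) mean(neg <= t), 0)
  # trapezoid over the full curve: points (FPR, TPR) from (1,1) to (0,0)
  fpr <- c(1, 1 - spec); tpr <- c(1, sens)
  auc_trap <- sum((fpr[-length(fpr)] - fpr[-1]) *
                    (tpr[-length(tpr)] + tpr[-1]) / 2)
  pl <- delong_placements(pos, neg)
  if (abs(auc_trap - pl$auc) > 1e-12)
    stop("internal error: trapezoidal and rank AUC disagree")
  thresholds <- if (orientation == "higher_is_positive") thr_eff
                else sort(-thr_eff)
  res <- structure(list(
    name = name, orientation = orientation,
    thresholds = thresholds,
    sensitivity = if (orientation == "higher_is_positive") sens
                  else rev(sens),
    specificity = if (orientation == "higher_is_positive") spec
                  else rev(spec),
    auc = pl$auc, auc_ci95 = NULL,
    n_positive = length(pos), n_negative = length(neg),
    scores_positive = pos, scores_negative = neg),
    class = "roc_result")
  res$auc_ci95 <- delong_ci(res)
  res
}

as_binary_outcome <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1, NA))) abort_validation("numeric labels must be 0/1")
    return(labels == 1)
  }
  v <- as.character(labels)
  if (!all(is.na(v) | v %in% OUTCOME_LEVELS))
    abort_validation("labels must be logical, 0/1, or survived/died")
  v == "died"
}

#' @export
print.roc_result <- function(x, ...) {
  ci <- x$auc_ci95
  cat(sprintf("<roc '%s'> AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$name, x$auc, ci[1], ci[2], x$n_positive, x$n_negative))
  invisible(x)
}

#' DeLong confidence interval for an AUC
#'
#' Variance from the DeLong structural components (sample variances of the
#' per-subject placement values over positives and negatives), Wald interval
#' on the AUC scale truncated to `[0, 1]`. A degenerate AUC of exactly 0 or
#' 1 yields a zero-width interval with a warning.
#'
#' @param roc A `roc_result` with at least 2 records per class.
#' @param level Confidence level (default 0.95).
#' @return `c(low, high)`.
#' @export
delong_ci <- function(roc, level = 0.95) {
  stopifnot(inherits(roc, "roc_result"))
  if (roc$n_positive < 2L || roc$n_negative < 2L)
    abort_validation("delong_ci needs at least 2 records per class")
  pl <- delong_placements(roc$scores_positive, roc$scores_negative)
  v <- stats::var(pl$v10) / roc$n_positive +
       stats::var(pl$v01) / roc$n_negative
  if (roc$auc %in% c(0, 1) && v == 0) {
    warning("degenerate AUC of exactly ", roc$auc,
            ": zero-width confidence interval")
    return(c(roc$auc, roc$auc))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- max(0, roc$auc - z * sqrt(v))
  hi <- min(1, roc$auc + z * sqrt(v))
  c(lo, hi)
}

#' Youden-optimal cut point
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' observed scores (giving half-integer cut points for integer-valued
#' scores). A record is predicted positive when its score exceeds the cut
#' point. Returns the candidate maximizing Youden's J = sensitivity +
#' specificity - 1; ties are broken toward higher specificity, then toward
#' the lower threshold.
#'
#' @param roc A `roc_result`.
#' @return Object of class `cut_point_result`: `cut_point`, `sensitivity`,
#'   `specificity`, `youden_j`.
#' @export
youden_cut_point <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  higher <- roc$orientation == "higher_is_positive"
  pos <- roc$scores_positive; neg <- roc$scores_negative
  vals <- sort(unique(c(pos, neg)))   # effective scale (already negated if lower)
  cand <- if (length(vals) > 1L) (vals[-1] + vals[-length(vals)]) / 2
          else vals
  sens <- vapply(cand, function(t) mean(pos > t), 0)
  spec <- vapply(cand, function(t) mean(neg <= t), 0)
  j <- sens + spec - 1
  cut_eff <- cand
  # map back to original scale for lower_is_positive scores
  cut_orig <- if (higher) cut_eff else -cut_eff
  ord <- order(-j, -spec, cut_orig)
  best <- ord[1]
  structure(list(cut_point = cut_orig[best], sensitivity = sens[best],
                 specificity = spec[best], youden_j = j[best]),
            class = "cut_point_result")
}

#' @export
print.cut_point_result <- function(x, ...) {
  cat(sprintf("cut point %.4g: sensitivity %.2f, specificity %.2f (J = %.2f)\n",
              x$cut_point, x$sensitivity, x$specificity, x$youden_j))
  invisible(x)
}

#' Paired DeLong test for two correlated ROC curves
#'
#' Two-sided test of equal AUC for two scores measured on the same records,
#' using the paired DeLong covariance of placement values. Records missing
#' either score (or the label) are dropped pairwise. Identical score vectors
#' give `z = 0`, `p = 1` exactly.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Binary outcomes (as in [roc_curve()]).
#' @param orientation Orientation applied to both scores.
#' @return List with `auc_a`, `auc_b`, `z`, `p`, `n_positive`, `n_negative`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels,
                               orientation = c("higher_is_positive",
                                               "lower_is_positive")) {
  orientation <- match.arg(orientation)
  lab <- as_binary_outcome(labels)
  ok <- !is.na(scores_a) & !is.na(scores_b) & !is.na(lab)
  a <- as.numeric(scores_a)[ok]; b <- as.numeric(scores_b)[ok]; y <- lab[ok]
  if (sum(y) < 2L || sum(!y) < 2L)
    abort_validation("delong_paired_test needs >= 2 records per class after pairwise deletion")
  if (orientation == "lower_is_positive") { a <- -a; b <- -b }
  pa <- delong_placements(a[y], a[!y])
  pb <- delong_placements(b[y], b[!y])
  m <- sum(y); n <- sum(!y)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  z <- if (d == 0) 0 else if (v <= 0) sign(d) * Inf else d / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = p_from_z(z),
       n_positive = m, n_negative = n)
}

#' Clinical-usefulness threshold
#'
#' A prognostic score is conventionally called clinically useful when its
#' ROC AUC reaches 0.8.
#'
#' @param auc AUC value(s) in `[0, 1]`.
#' @return Logical: `auc >= 0.8`.
#' @export
clinically_useful <- function(auc) {
  if (any(auc < 0 | auc > 1, na.rm = TRUE))
    abort_validation("auc must lie in [0, 1]")
  auc >= 0.8
}

#' ROC summary table for a score panel
#'
#' One row per score: AUC, DeLong 95% CI, Youden cut point, sensitivity and
#' specificity -- the standard ROC comparison table for a severity-score
#' panel.
#'
#' @param panel A `score_panel` from [compute_panel()].
#' @param labels Outcomes aligned with the panel rows.
#' @param score_names Columns to analyse (default all shipped scores).
#' @return Data.frame with columns `score`, `auc`, `ci_low`, `ci_high`,
#'   `cut_point`, `sensitivity`, `specificity`, `n_positive`, `n_negative`.
#' @export
roc_table <- function(panel, labels, score_names = panel_score_names()) {
  rows <- lapply(score_names, function(nm) {
    if (!nm %in% names(panel)) return(NULL)
    roc <- roc_curve(panel[[nm]], labels, name = nm)
    cp <- youden_cut_point(roc)
    data.frame(score = nm, auc = roc$auc,
               ci_low = roc$auc_ci95[1], ci_high = roc$auc_ci95[2],
               cut_point = cp$cut_point, sensitivity = cp$sensitivity,
               specificity = cp$specificity,
               n_positive = roc$n_positive, n_negative = roc$n_negative,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  out[order(-out$auc), , drop = FALSE]
}
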