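test_that("a perfectly separating score gives AUC 1, J = 1 and a degenerate CI", {
  scores <- c(1, 2, 3, 11, 12, 13)
  labels <- c(0, 0, 0, 1, 1, 1)
  expect_warning(roc <- roc_curve(scores, labels), "degenerate")
  expect_equal(roc$auc, 1)
  expect_equal(roc$auc_ci95, c(1, 1))
  cp <- youden_cut_point(roc)
  expect_equal(cp$youden_j, 1)
  expect_equal(cp$cut_point, 7)   # midpoint between the separated groups
})

test_that("single-class input is rejected", {
  expect_error(roc_curve(1:5, rep(1, 5)), "positive and")
})

test_that("AUC equals brute-force pair counting on tie-rich random fixtures", {
  set.seed(101)
  for (rep in 1:50) {
    n <- 50
    scores <- sample(seq(0, 10, 0.5), n, TRUE)   # heavy ties
    labels <- runif(n) < 0.4
    if (sum(labels) < 2 || sum(!labels) < 2) next
    roc <- roc_curve(scores, labels)
    expect_equal(roc$auc, auc_pair_count(scores[labels], scores[!labels]),
                 tolerance = 1e-12)
  }
})

test_that("the Youden cut equals exhaustive threshold search", {
  set.seed(102)
  for (rep in 1:20) {
    scores <- round(rnorm(100, 10, 3), 1)
    labels <- runif(100) < plogis((scores - 10) / 2)
    if (sum(labels) < 2 || sum(!labels) < 2) next
    roc <- roc_curve(scores, labels)
    cp <- youden_cut_point(roc)
    # exhaustive search over the candidate set (midpoints between distinct
    # observed scores)
    u <- sort(unique(scores))
    cand <- (u[-1] + u[-length(u)]) / 2
    j <- vapply(cand, function(t)
      mean(scores[labels] > t) + mean(scores[!labels] <= t) - 1, 0)
    expect_equal(cp$youden_j, max(j), tolerance = 1e-12)
  }
})

test_that("integer scores yield half-integer cut points", {
  # a score that separates best between 13 and 14
  scores <- c(9, 10, 11, 12, 13, 13, 14, 15, 16, 17, 18, 14)
  labels <- c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 0)
  cp <- youden_cut_point(roc_curve(scores, labels))
  expect_equal(cp$cut_point, 13.5)
})

test_that("reversing orientation maps AUC to 1 - AUC and swaps sens/spec", {
  set.seed(103)
  scores <- rnorm(80); labels <- runif(80) < plogis(scores)
  hi <- roc_curve(scores, labels, "higher_is_positive")
  lo <- roc_curve(scores, labels, "lower_is_positive")
  expect_equal(lo$auc, 1 - hi$auc, tolerance = 1e-12)
  # with distinct scores the reversed curve's operating points are the
  # complements of the original's, offset by one threshold at the boundary
  expect_equal(sort(lo$sensitivity)[-1],
               sort(1 - hi$sensitivity)[-length(hi$sensitivity)])
  expect_equal(utils::head(sort(lo$specificity), -1),
               sort(1 - hi$specificity)[-1])
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(104)
  scores <- rlnorm(60); labels <- runif(60) < 0.4
  if (sum(labels) < 2) labels[1:2] <- TRUE
  base <- roc_curve(scores, labels)$auc
  expect_equal(roc_curve(log(scores), labels)$auc, base)
  expect_equal(roc_curve(scores^3, labels)$auc, base)
  expect_equal(roc_curve(exp(scores / max(scores)), labels)$auc, base)
})

test_that("a label-independent score has AUC near one half", {
  set.seed(105)
  scores <- rnorm(2000)
  labels <- runif(2000) < 0.5
  expect_lt(abs(roc_curve(scores, labels)$auc - 0.5), 0.03)
})

test_that("AUC, DeLong CI and paired test agree with pROC", {
  library(pROC)
  set.seed(106)
  n <- 150
  a <- rnorm(n); y <- runif(n) < plogis(a)
  b <- a + rnorm(n, sd = 1.5)
  if (sum(y) < 2 || sum(!y) < 2) y[1:3] <- c(TRUE, TRUE, FALSE)
  roc_mine <- roc_curve(a, y)
  roc_ref <- pROC::roc(response = y, predictor = a, quiet = TRUE,
                       direction = "<")
  expect_equal(roc_mine$auc, as.numeric(pROC::auc(roc_ref)), tolerance = 1e-12)
  ci_ref <- as.numeric(pROC::ci.auc(roc_ref, method = "delong"))
  expect_equal(roc_mine$auc_ci95, ci_ref[c(1, 3)], tolerance = 1e-10)
  ref_test <- pROC::roc.test(
    roc_ref, pROC::roc(response = y, predictor = b, quiet = TRUE,
                       direction = "<"),
    method = "delong", paired = TRUE)
  mine <- delong_paired_test(a, b, y)
  expect_equal(mine$p, ref_test$p.value, tolerance = 1e-10)
  expect_equal(mine$z, unname(ref_test$statistic), tolerance = 1e-10)
})

test_that("the paired DeLong test is exactly null for identical curves", {
  set.seed(107)
  s <- rnorm(50); y <- runif(50) < 0.5
  if (sum(y) < 2 || sum(!y) < 2) y[1:3] <- c(TRUE, TRUE, FALSE)
  res <- delong_paired_test(s, s, y)
  expect_identical(res$z, 0)
  expect_equal(res$p, 1)
})

test_that("duplicating every record roughly halves the DeLong variance", {
  set.seed(108)
  s <- rnorm(120); y <- runif(120) < plogis(s)
  roc1 <- roc_curve(s, y)
  roc2 <- roc_curve(c(s, s), c(y, y))
  w1 <- diff(roc1$auc_ci95); w2 <- diff(roc2$auc_ci95)
  # CI width scales with sqrt(var): expect ~1/sqrt(2), allow 10%
  expect_lt(abs(w2 / w1 - 1 / sqrt(2)), 0.1 / sqrt(2))
})

test_that("missing scores are dropped pairwise before curve construction", {
  scores <- c(NA, 1, 2, 3, 4, NA, 5)
  labels <- c(1, 0, 1, 0, 1, 0, 1)
  roc <- roc_curve(scores, labels)
  expect_equal(roc$n_positive + roc$n_negative, 5)
})

test_that("the clinical-usefulness rule is a simple AUC threshold", {
  expect_true(clinically_useful(0.84))
  expect_true(clinically_useful(0.8))
  expect_false(clinically_useful(0.79))
  expect_error(clinically_useful(1.2), "0, 1")
})

test_that("roc_table reports one calibrated row per score", {
  cfg <- default_configs()$glasgow
  ch <- simulate_cohort(cfg, seed = 9)
  panel <- compute_panel(ch, encephalopathy_mode = "observed")
  tab <- roc_table(panel, ch$icu_outcome)
  expect_setequal(tab$score, panel_score_names())
  expect_true(all(tab$ci_low <= tab$auc & tab$auc <= tab$ci_high))
  expect_true(all(tab$sensitivity >= 0 & tab$sensitivity <= 1))
  expect_false(is.unsorted(rev(tab$auc)))   # sorted by decreasing AUC
})
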