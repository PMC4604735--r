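# Shared fixtures: compact record builders and independent mini-oracles used
# across the suite. Everything is generated in code at test time.

# One fully observed, clinically plausible record; fields overridable.
make_record <- function(...) {
  rec <- list(
    patient_id = "p1", age = 50, sex = "male", sodium = 136, potassium = 4.1,
    urea = 8, lactate = 1.9, creatinine = 81, wcc = 13, bilirubin = 45,
    pt_ratio = 1.5, albumin = 22, platelets = 140, pao2 = 12.4,
    pf_ratio = 22, gcs = 14, map = 75, noradrenaline_dose = 0,
    ascites = "none", encephalopathy = 0, alcoholic_aetiology = TRUE,
    icu_outcome = "survived")
  mods <- list(...)
  rec[names(mods)] <- mods
  rec
}

make_cohort_df <- function(n, seed = 1) {
  set.seed(seed)
  df <- do.call(rbind, lapply(seq_len(n), function(i)
    as.data.frame(make_record(patient_id = sprintf("p%03d", i)),
                  stringsAsFactors = FALSE)))
  df$lactate <- round(exp(rnorm(n, log(1.9), 0.5)), 2)
  df$bilirubin <- round(exp(rnorm(n, log(45), 1.0)), 1)
  df$pt_ratio <- round(exp(rnorm(n, log(1.5), 0.35)), 2)
  df$albumin <- round(pmax(8, rnorm(n, 22, 6)), 1)
  df$ascites <- sample(c("none", "mild", "severe"), n, TRUE)
  df$encephalopathy <- sample(0:4, n, TRUE)
  df$icu_outcome <- sample(c("survived", "died"), n, TRUE, prob = c(0.7, 0.3))
  df
}

# Brute-force pair-counting AUC: P(pos > neg) + P(pos = neg)/2.
auc_pair_count <- function(pos, neg) {
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Fast rank AUC for bootstrap loops.
auc_rank <- function(scores, died) {
  r <- rank(scores)
  m <- sum(died); n <- sum(!died)
  (sum(r[died]) - m * (m + 1) / 2) / (m * n)
}

# Independent linear-scan band evaluator (left-closed, right-open bands).
band_points_scan <- function(value, edges, points) {
  if (is.na(value)) return(NA_real_)
  i <- 1L
  for (e in edges) if (value >= e) i <- i + 1L else break
  points[i]
}

# Quantile type-7 oracle: linear interpolation between closest order stats.
quantile_type7_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
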