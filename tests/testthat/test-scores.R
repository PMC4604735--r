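# Representative values for each CTP component band, used to enumerate all
# 3^5 combinations.
ctp_band_values <- list(
  bilirubin = c(20, 40, 71),
  albumin = c(36, 30, 19.8),
  pt_ratio = c(1.2, 1.8, 2.5),
  ascites = c("none", "mild", "severe"),
  encephalopathy = c(0, 2, 4))

test_that("CTP component bands honour the published boundaries", {
  expect_equal(ctp_component_points("bilirubin", c(33.9, 34, 40, 50, 50.1)),
               c(1L, 2L, 2L, 2L, 3L))
  expect_equal(ctp_component_points("albumin", c(36, 35, 28, 27.9)),
               c(1L, 2L, 2L, 3L))
  expect_equal(ctp_component_points("inr", c(1.5, 1.70, 1.71, 2.30, 2.31)),
               c(1L, 1L, 2L, 2L, 3L))
  expect_equal(ctp_component_points("ascites", c("none", "mild", "severe")),
               c(1L, 2L, 3L))
  expect_equal(ctp_component_points("encephalopathy", c(0, 1, 2, 3, 4)),
               c(1L, 2L, 2L, 3L, 3L))
  expect_true(is.na(ctp_component_points("bilirubin", NA)))
})

test_that("CTP equals its component sum over all 3^5 band combinations", {
  grid <- expand.grid(b = 1:3, a = 1:3, i = 1:3, asc = 1:3, enc = 1:3)
  recs <- data.frame(
    patient_id = paste0("g", seq_len(nrow(grid))),
    bilirubin = ctp_band_values$bilirubin[grid$b],
    albumin = ctp_band_values$albumin[grid$a],
    pt_ratio = ctp_band_values$pt_ratio[grid$i],
    ascites = ctp_band_values$ascites[grid$asc],
    encephalopathy = ctp_band_values$encephalopathy[grid$enc],
    icu_outcome = "survived", stringsAsFactors = FALSE)
  observed <- compute_ctp(recs, "observed")
  expect_equal(observed, grid$b + grid$a + grid$i + grid$asc + grid$enc)
  expect_true(all(observed >= 5 & observed <= 15))
  # excluded mode drops exactly the encephalopathy points, for every combination
  excluded <- compute_ctp(recs, "excluded")
  expect_equal(observed - excluded, grid$enc)
  # presumed mode awards 2 points regardless of the recorded grade
  presumed <- compute_ctp(recs, "presumed_2")
  expect_equal(presumed - excluded, rep(2, nrow(grid)))
})

test_that("a representative worst-band record scores 13 by component sum", {
  rec <- make_record(bilirubin = 71, albumin = 19.8, pt_ratio = 1.8,
                     ascites = "severe", encephalopathy = 2)
  expect_equal(compute_ctp(as.data.frame(rec)), 13)
})

test_that("CTP+L is CTP plus raw lactate, exactly, and propagates missingness", {
  expect_equal(compute_ctp_plus_l(as.data.frame(make_record(
    bilirubin = 20, albumin = 40, pt_ratio = 1.2, ascites = "none",
    encephalopathy = 0, lactate = 0.5))), 5.5)
  expect_equal(compute_ctp_plus_l(as.data.frame(make_record(
    bilirubin = 71, albumin = 19.8, pt_ratio = 2.5, ascites = "severe",
    encephalopathy = 4, lactate = 4.1))), 19.1)
  expect_true(is.na(compute_ctp_plus_l(as.data.frame(
    make_record(lactate = NA)))))
  # identity over many random records
  df <- make_cohort_df(500, seed = 21)
  expect_equal(compute_ctp_plus_l(df) - compute_ctp(df), df$lactate)
})

test_that("worsening any single CTP component never decreases the score", {
  base <- as.data.frame(make_record(bilirubin = 20, albumin = 36,
                                    pt_ratio = 1.2, ascites = "none",
                                    encephalopathy = 0))
  for (comp in names(ctp_band_values)) {
    for (k in 1:2) {
      worse <- base
      worse[[comp]] <- ctp_band_values[[comp]][k + 1]
      better <- base
      better[[comp]] <- ctp_band_values[[comp]][k]
      expect_gte(compute_ctp(worse), compute_ctp(better))
    }
  }
})

test_that("band sums equal an independent linear-scan evaluation", {
  defs <- default_score_definitions()
  df <- derived_fields(make_cohort_df(60, seed = 31))
  for (nm in c("sofa", "clif_sofa", "apache_ii")) {
    def <- defs[[nm]]
    expected <- vapply(seq_len(nrow(df)), function(i) {
      tot <- def$offset
      for (comp in def$components) {
        v <- as.numeric(df[[comp$field]][i])
        pts <- band_points_scan(v, as.numeric(comp$edges),
                                as.numeric(comp$points))
        if (is.na(pts) && !is.null(comp$missing_points))
          pts <- comp$missing_points
        tot <- tot + pts
      }
      if (!is.null(def$bounds)) tot <- min(max(tot, def$bounds[1]), def$bounds[2])
      tot
    }, 0)
    expect_equal(compute_defined_score(df, def), expected, info = nm)
  }
})

test_that("SOFA spans its bounds at the extreme bands", {
  worst <- as.data.frame(make_record(
    pf_ratio = 5, platelets = 10, bilirubin = 300, noradrenaline_dose = 0.5,
    gcs = 3, creatinine = 500))
  best <- as.data.frame(make_record(
    pf_ratio = 60, pao2 = 60, platelets = 300, bilirubin = 10,
    noradrenaline_dose = 0, map = 80, gcs = 15, creatinine = 80))
  sofa <- default_score_definitions()$sofa
  expect_equal(compute_defined_score(worst, sofa), 24)
  expect_equal(compute_defined_score(best, sofa), 0)
})

test_that("degenerate definitions evaluate to their closed forms", {
  flat <- score_definition("flat", "linear_predictor",
                           components = list(list(field = "lactate",
                                                  coefficient = 0)),
                           intercept = 7)
  df <- make_cohort_df(10, seed = 41)
  expect_equal(compute_defined_score(df, flat), rep(7, 10))

  twoband <- score_definition("twoband", "band_sum",
                              components = list(list(field = "lactate",
                                                     edges = 10,
                                                     points = c(0, 4))))
  expect_equal(compute_defined_score(
    as.data.frame(make_record(lactate = 11)), twoband), 4)
  expect_equal(compute_defined_score(
    as.data.frame(make_record(lactate = 9)), twoband), 0)
})

test_that("MELD matches a hand-computed value with its input clamps", {
  rec <- as.data.frame(make_record(bilirubin = 85.5, creatinine = 442,
                                   pt_ratio = 2.0))
  # bilirubin 85.5/17.1 = 5 mg/dL; creatinine 442/88.4 = 5 -> capped at 4
  by_hand <- 3.78 * log(5) + 11.2 * log(2) + 9.57 * log(4) + 6.43
  expect_equal(compute_defined_score(rec, default_score_definitions()$meld),
               by_hand, tolerance = 1e-10)
  # sub-normal inputs floored at 1 before the log
  lo <- as.data.frame(make_record(bilirubin = 5, creatinine = 40,
                                  pt_ratio = 0.9))
  expect_equal(compute_defined_score(lo, default_score_definitions()$meld),
               6.43, tolerance = 1e-10)
})

test_that("definition validation rejects malformed structures", {
  expect_error(score_definition("bad", "band_sum", components = list(
    list(field = "lactate", edges = c(2, 1), points = c(1, 2, 3)))),
    "increasing")
  expect_error(score_definition("bad", "band_sum", components = list(
    list(field = "lactate", edges = 1, points = c(1, -2)))),
    "points")
  expect_error(score_definition("bad", "band_sum", components = list(
    list(field = "nonexistent", edges = 1, points = c(0, 1)))),
    "field")
  expect_error(score_definition("bad", "linear_predictor", components = list(
    list(field = "lactate", coefficient = "x"))), "coefficient")
})

test_that("the panel propagates missing components score-by-score", {
  rec <- make_record(ascites = NA)
  panel <- compute_panel(as.data.frame(rec))
  expect_true(is.na(panel$ctp))
  expect_true(is.na(panel$ctp_plus_l))
  expect_false(is.na(panel$meld))
  full <- compute_panel(as.data.frame(make_record()))
  expect_false(anyNA(full[panel_score_names()]))
})

test_that("the panel is insensitive to record order", {
  df <- make_cohort_df(30, seed = 51)
  p1 <- compute_panel(df)
  perm <- sample(nrow(df))
  p2 <- compute_panel(df[perm, ])
  expect_equal(p2[order(perm), panel_score_names()],
               p1[, panel_score_names()], ignore_attr = TRUE)
})

test_that("presumed-grade mode feeds grade 2 to every encephalopathy consumer", {
  df <- make_cohort_df(20, seed = 61)
  df$encephalopathy <- NULL    # grades not collected
  panel <- compute_panel(df, encephalopathy_mode = "presumed_2")
  expect_false(anyNA(panel$ctp))
  expect_false(anyNA(panel$clif_sofa))
  expect_error(compute_panel(df, encephalopathy_mode = "observed"))
})
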