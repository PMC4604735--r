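# The severity-score engine: the fixed CTP / CTP+L band table, generic
# evaluation of declarative score definitions, and the per-patient panel.

#' CTP component points
#'
#' Points (1-3) for one Child-Turcotte-Pugh component. Band closure at the
#' printed boundaries: bilirubin band 2 is `[34, 50]` umol/L; albumin band 2
#' is `[28, 35]` g/L; INR/PT-ratio band 1 is `<= 1.70` and band 2 is
#' `(1.70, 2.30]`, so the bands are exhaustive. Ascites none/mild/severe and
#' encephalopathy none / grade I-II / grade III-IV map to 1/2/3.
#'
#' @param component One of `"bilirubin"`, `"albumin"`, `"inr"`, `"ascites"`,
#'   `"encephalopathy"`.
#' @param value Numeric vector (ascites may be character/factor with levels
#'   none/mild/severe; encephalopathy is the 0-4 West Haven grade).
#' @return Integer vector of points in 1-3; `NA` where the value is missing.
#' @export
#' @examples
#' ctp_component_points("bilirubin", c(20, 34, 50, 51))
ctp_component_points <- function(component = c("bilirubin", "albumin", "inr",
                                               "ascites", "encephalopathy"),
                                 value) {
  component <- match.arg(component)
  if (component == "ascites") {
    v <- check_levels(value, ASCITES_LEVELS, "ascites")
    return(as.integer(v))
  }
  v <- as.numeric(value)
  pts <- switch(component,
    bilirubin = ifelse(v < 34, 1L, ifelse(v <= 50, 2L, 3L)),
    albumin = ifelse(v > 35, 1L, ifelse(v >= 28, 2L, 3L)),
    inr = ifelse(v <= 1.70, 1L, ifelse(v <= 2.30, 2L, 3L)),
    encephalopathy = {
      bad <- !is.na(v) & !(v %in% 0:4)
      if (any(bad))
        abort_validation(sprintf("encephalopathy grade %s outside 0-4",
                                 v[which(bad)[1]]))
      ifelse(v == 0, 1L, ifelse(v <= 2, 2L, 3L))
    })
  as.integer(pts)
}

#' Child-Turcotte-Pugh score
#'
#' Sum of the five CTP component points (bilirubin, albumin, INR/PT ratio,
#' ascites, encephalopathy), range 5-15. Because pre-intubation
#' encephalopathy grades are not always collectable, three modes are
#' supported: `"observed"` uses the recorded grade; `"presumed_2"` awards 2
#' points for encephalopathy regardless of the record; `"excluded"` sums
#' only the other four components (range 4-12).
#'
#' @param x A `cohort`, data.frame of records, or single record (1-row list).
#' @param encephalopathy_mode `"observed"`, `"presumed_2"` or `"excluded"`.
#' @return Numeric vector, one score per record; `NA` where any required
#'   component is missing.
#' @export
compute_ctp <- function(x, encephalopathy_mode = c("observed", "presumed_2",
                                                   "excluded")) {
  mode <- match.arg(encephalopathy_mode)
  df <- as.data.frame(x)
  need <- c("bilirubin", "albumin", "pt_ratio", "ascites")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    abort_validation(paste("records lack CTP component field(s):",
                           paste(missing_cols, collapse = ", ")))
  total <- ctp_component_points("bilirubin", df$bilirubin) +
    ctp_component_points("albumin", df$albumin) +
    ctp_component_points("inr", df$pt_ratio) +
    ctp_component_points("ascites", df$ascites)
  enc <- switch(mode,
    observed = {
      if (!"encephalopathy" %in% names(df))
        abort_validation("records lack encephalopathy grades (mode=observed)")
      ctp_component_points("encephalopathy", df$encephalopathy)
    },
    presumed_2 = rep(2L, nrow(df)),
    excluded = rep(0L, nrow(df)))
  as.numeric(total + enc)
}

#' CTP + lactate score
#'
#' The CTP score plus the raw admission arterial lactate concentration in
#' mmol/L (no banding, no rounding), so `CTP+L - CTP = lactate` exactly.
#'
#' @inheritParams compute_ctp
#' @return Numeric vector; `NA` where CTP or lactate is missing.
#' @export
compute_ctp_plus_l <- function(x, encephalopathy_mode = c("observed",
                                                          "presumed_2",
                                                          "excluded")) {
  df <- as.data.frame(x)
  if (!"lactate" %in% names(df))
    abort_validation("records lack a lactate field")
  compute_ctp(df, encephalopathy_mode) + df$lactate
}

#' Evaluate a declarative score definition
#'
#' Band sums add per-component band points (left-closed bands over ascending
#' edges) plus the definition's constant offset; linear predictors add
#' intercept plus coefficient times the (optionally clamped, optionally
#' log-transformed) component value. Unit conversions are carried by derived
#' fields ([derived_fields()]). A missing component input makes the score
#' missing unless the component declares `missing_points`.
#'
#' @param x Records (`cohort`, data.frame, or 1-row list).
#' @param definition A [score_definition()].
#' @return Numeric vector, one value (or `NA`) per record.
#' @export
compute_defined_score <- function(x, definition) {
  stopifnot(inherits(definition, "score_definition"))
  df <- derived_fields(as.data.frame(x))
  n <- nrow(df)
  total <- rep(if (definition$kind == "band_sum") definition$offset
               else definition$intercept, n)
  for (comp in definition$components) {
    if (!comp$field %in% names(df))
      abort_validation(sprintf("records lack field '%s' needed by score '%s'",
                               comp$field, definition$name))
    v <- as.numeric(df[[comp$field]])
    if (definition$kind == "band_sum") {
      pts <- as.numeric(comp$points)[findInterval(v, as.numeric(comp$edges)) + 1L]
      if (!is.null(comp$missing_points))
        pts[is.na(v)] <- comp$missing_points
      total <- total + pts
    } else {
      if (!is.null(comp$floor)) v <- pmax(v, comp$floor)
      if (!is.null(comp$cap)) v <- pmin(v, comp$cap)
      if ((comp$transform %||% "identity") == "log") {
        bad <- !is.na(v) & v <= 0
        if (any(bad)) {
          i <- which(bad)[1]
          id <- if ("patient_id" %in% names(df)) df$patient_id[i] else i
          abort_validation(sprintf(
            "score '%s': log of non-positive %s (%g) for patient %s",
            definition$name, comp$field, v[i], id))
        }
        v <- log(v)
      }
      total <- total + comp$coefficient * v
    }
  }
  if (!is.null(definition$bounds))
    total <- pmin(pmax(total, definition$bounds[1]), definition$bounds[2])
  as.numeric(total)
}

#' Compute the full severity-score panel
#'
#' One row per patient with CTP, CTP+L and every supplied definition
#' (default panel: MELD, UKELD, SOFA, CLIF-SOFA, APACHE II, RFH). With
#' `encephalopathy_mode = "presumed_2"` the recorded grade is replaced by
#' grade 2 throughout -- for CTP/CTP+L and for definitions that score
#' encephalopathy (CLIF-SOFA) -- emulating cohorts where pre-intubation
#' grades were not collected. Deterministic and insensitive to record order.
#'
#' @param x A `cohort` or record data.frame.
#' @param definitions Named list of [score_definition()]s
#'   (default [default_score_definitions()]).
#' @param encephalopathy_mode See [compute_ctp()].
#' @return A data.frame of class `score_panel`: `patient_id`, `ctp`,
#'   `ctp_plus_l`, then one column per definition; `NA` marks a score whose
#'   required inputs are missing.
#' @export
compute_panel <- function(x, definitions = default_score_definitions(),
                          encephalopathy_mode = c("observed", "presumed_2",
                                                  "excluded")) {
  mode <- match.arg(encephalopathy_mode)
  df <- as.data.frame(x)
  if (mode == "presumed_2")
    df$encephalopathy <- 2
  panel <- data.frame(
    patient_id = if ("patient_id" %in% names(df)) df$patient_id
                 else as.character(seq_len(nrow(df))),
    ctp = compute_ctp(df, mode),
    ctp_plus_l = compute_ctp_plus_l(df, mode),
    stringsAsFactors = FALSE)
  for (nm in names(definitions))
    panel[[nm]] <- compute_defined_score(df, definitions[[nm]])
  class(panel) <- c("score_panel", "data.frame")
  panel
}

#' Names of the shipped score columns
#' @return Character vector in panel column order.
#' @export
panel_score_names <- function() {
  c("ctp", "ctp_plus_l", "meld", "ukeld", "sofa", "clif_sofa",
    "apache_ii", "rfh")
}
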