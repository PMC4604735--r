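# Declarative severity-score definitions: banded point sums (SOFA-family,
# APACHE II) and log-linear predictors (MELD, UKELD, RFH), shipped as YAML
# documents and validated structurally before use.

#' Construct / validate a score definition
#'
#' A `score_definition` is either a `band_sum` (each component maps a record
#' field through ascending band edges to integer points, summed, plus an
#' optional constant offset) or a `linear_predictor` (intercept plus
#' coefficient times identity- or log-transformed component values, with
#' optional per-component floor/cap clamps applied before the transform).
#'
#' Band convention: `edges` are the ascending lower bounds of bands 2..k, so
#' a value `v` scores `points[i]` where `i` counts edges `<= v` plus one
#' (bands are left-closed, right-open). Components may name canonical record
#' fields or derived fields (see [derived_fields()]). A component with
#' `missing_points` set contributes that many points when its input is
#' missing ("normal-if-missing", the APACHE II physiology convention);
#' otherwise a missing input makes the whole score missing.
#'
#' @param name Score name.
#' @param kind `"band_sum"` or `"linear_predictor"`.
#' @param components List of component lists. For `band_sum`:
#'   `list(field=, edges=, points=, missing_points=NULL)`. For
#'   `linear_predictor`: `list(field=, coefficient=, transform="identity"|"log",
#'   floor=NULL, cap=NULL)`.
#' @param intercept Intercept (linear predictors).
#' @param offset Constant added to a band sum (e.g. chronic-health points).
#' @param bounds Optional `c(min, max)` clamp on the total.
#' @param source Citation string.
#' @param provisional Logical; marks definitions transcribed provisionally.
#' @return A validated object of class `score_definition`.
#' @export
score_definition <- function(name, kind = c("band_sum", "linear_predictor"),
                             components, intercept = 0, offset = 0,
                             bounds = NULL, source = "", provisional = FALSE) {
  kind <- match.arg(kind)
  def <- structure(list(name = name, kind = kind, components = components,
                        intercept = intercept, offset = offset,
                        bounds = bounds, source = source,
                        provisional = isTRUE(provisional)),
                   class = "score_definition")
  validate_score_definition(def)
}

known_score_fields <- function() c(COHORT_FIELDS, DERIVED_FIELD_NAMES)

validate_score_definition <- function(def) {
  if (!length(def$components))
    abort_validation(sprintf("score '%s' has no components", def$name))
  for (comp in def$components) {
    if (is.null(comp$field) || !comp$field %in% known_score_fields())
      abort_validation(sprintf(
        "score '%s': component field '%s' is not a patient-record or derived field",
        def$name, comp$field %||% "<missing>"))
    if (def$kind == "band_sum") {
      edges <- as.numeric(comp$edges)
      points <- as.numeric(comp$points)
      if (length(edges) < 1L || is.unsorted(edges, strictly = TRUE))
        abort_validation(sprintf(
          "score '%s', component '%s': band edges must be strictly increasing",
          def$name, comp$field))
      if (length(points) != length(edges) + 1L)
        abort_validation(sprintf(
          "score '%s', component '%s': need one more point value than edges",
          def$name, comp$field))
      if (any(points < 0) || any(points != round(points)))
        abort_validation(sprintf(
          "score '%s', component '%s': band points must be integers >= 0",
          def$name, comp$field))
      if (!is.null(comp$missing_points) &&
          !comp$missing_points %in% points)
        abort_validation(sprintf(
          "score '%s', component '%s': missing_points must be one of the band points",
          def$name, comp$field))
    } else {
      if (!is_scalar_number(comp$coefficient))
        abort_validation(sprintf(
          "score '%s', component '%s': coefficient must be a number",
          def$name, comp$field))
      if (!(comp$transform %||% "identity") %in% c("identity", "log"))
        abort_validation(sprintf(
          "score '%s', component '%s': transform must be identity or log",
          def$name, comp$field))
    }
  }
  if (!is.null(def$bounds) &&
      (length(def$bounds) != 2L || def$bounds[1] > def$bounds[2]))
    abort_validation(sprintf("score '%s': bounds must be c(min, max)", def$name))
  def
}

#' @export
print.score_definition <- function(x, ...) {
  cat(sprintf("<score_definition '%s'> %s, %d components%s\n", x$name, x$kind,
              length(x$components),
              if (x$provisional) " [provisional]" else ""))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Load a score definition from YAML or JSON
#'
#' @param path Definition file (see `inst/extdata/score_definitions/` for the
#'   shipped set and schema).
#' @return A `score_definition`.
#' @export
load_score_definition <- function(path) {
  doc <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  score_definition(
    name = doc$name, kind = doc$kind, components = doc$components,
    intercept = doc$intercept %||% 0, offset = doc$offset %||% 0,
    bounds = if (!is.null(doc$bounds)) unlist(doc$bounds),
    source = doc$source %||% "", provisional = doc$provisional %||% FALSE)
}

#' The shipped score-definition panel
#'
#' Loads the six configuration-driven definitions (MELD, UKELD, SOFA,
#' CLIF-SOFA, APACHE II, RFH) shipped with the package. CTP and CTP+L are
#' fixed band tables implemented directly by [compute_ctp()] and
#' [compute_ctp_plus_l()] and are not configurable.
#'
#' The RFH definition is provisional: its primary-source coefficients are not
#' available here, so a synthetic linear predictor with the published input
#' set (log bilirubin, log lactate, PT ratio, urea, organ-failure count) is
#' shipped, scaled to the published score distribution's magnitude. The
#' APACHE II definition covers only the physiology variables in the collected
#' set; absent components score zero points (normal-if-missing).
#'
#' @return Named list of `score_definition` objects.
#' @export
default_score_definitions <- function() {
  dir <- system.file("extdata", "score_definitions", package = "ctpl")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  defs <- lapply(files, load_score_definition)
  names(defs) <- vapply(defs, `[[`, "", "name")
  defs[c("meld", "ukeld", "sofa", "clif_sofa", "apache_ii", "rfh")]
}

# ---- derived fields ---------------------------------------------------------

DERIVED_FIELD_NAMES <- c("pf_mmhg", "pao2_mmhg", "bilirubin_mgdl",
                         "creatinine_mgdl", "gcs_deficit", "cardio_support",
                         "organ_failures")

#' Derived fields used by score definitions
#'
#' Augments a record table with unit-converted and composite inputs:
#' `pf_mmhg`, `pao2_mmhg` (kPa times 7.50062), `bilirubin_mgdl` (/17.1),
#' `creatinine_mgdl` (/88.4), `gcs_deficit` (15 - GCS), `cardio_support`
#' (SOFA cardiovascular stage: 0 = MAP >= 70 and no vasopressor, 1 = MAP < 70,
#' 3 = noradrenaline at or below 0.1 ug/kg/min, 4 = above 0.1) and
#' `organ_failures` (count of failing organ systems under configurable
#' criteria, see [organ_failure_count()]).
#'
#' @param x A `cohort` or data.frame of records.
#' @return The data.frame with derived columns appended.
#' @export
derived_fields <- function(x) {
  df <- as.data.frame(x)
  get <- function(f) if (f %in% names(df)) df[[f]] else rep(NA_real_, nrow(df))
  df$pf_mmhg <- get("pf_ratio") * KPA_TO_MMHG
  df$pao2_mmhg <- get("pao2") * KPA_TO_MMHG
  df$bilirubin_mgdl <- get("bilirubin") / BILIRUBIN_UMOL_PER_MGDL
  df$creatinine_mgdl <- get("creatinine") / CREATININE_UMOL_PER_MGDL
  df$gcs_deficit <- 15 - get("gcs")
  map <- get("map"); nad <- get("noradrenaline_dose")
  nad0 <- ifelse(is.na(nad), 0, nad)  # no vasopressor recorded -> none given
  cardio <- ifelse(nad0 > 0.1, 4,
            ifelse(nad0 > 0, 3,
            ifelse(!is.na(map) & map < 70, 1, 0)))
  df$cardio_support <- cardio
  df$organ_failures <- organ_failure_count(df)
  df
}

#' Count failing organ systems
#'
#' Six-system count used by the RFH linear predictor: respiratory
#' (PaO2/FiO2 < 200 mmHg), coagulation (platelets < 50 or PT ratio > 2.5),
#' liver (bilirubin > 102 umol/L), renal (creatinine > 170 umol/L), cerebral
#' (GCS < 12 or encephalopathy grade III-IV), cardiovascular (MAP < 70 mmHg
#' or any noradrenaline). A criterion with missing inputs counts as not
#' failing. Thresholds are configurable.
#'
#' @param x Record data.frame.
#' @param criteria Named list of thresholds overriding the defaults
#'   (`pf_mmhg`, `platelets`, `pt_ratio`, `bilirubin`, `creatinine`, `gcs`,
#'   `encephalopathy`, `map`).
#' @return Integer vector of counts 0-6.
#' @export
organ_failure_count <- function(x, criteria = list()) {
  cr <- utils::modifyList(list(
    pf_mmhg = 200, platelets = 50, pt_ratio = 2.5, bilirubin = 102,
    creatinine = 170, gcs = 12, encephalopathy = 3, map = 70), criteria)
  df <- as.data.frame(x)
  get <- function(f) if (f %in% names(df)) df[[f]] else rep(NA_real_, nrow(df))
  pf <- if ("pf_mmhg" %in% names(df)) df$pf_mmhg else get("pf_ratio") * KPA_TO_MMHG
  tf <- function(v) !is.na(v) & v   # missing input -> criterion not met
  nad <- get("noradrenaline_dose")
  resp <- tf(pf < cr$pf_mmhg)
  coag <- tf(get("platelets") < cr$platelets) | tf(get("pt_ratio") > cr$pt_ratio)
  liver <- tf(get("bilirubin") > cr$bilirubin)
  renal <- tf(get("creatinine") > cr$creatinine)
  brain <- tf(get("gcs") < cr$gcs) | tf(get("encephalopathy") >= cr$encephalopathy)
  cardio <- tf(get("map") < cr$map) | tf(nad > 0)
  as.integer(resp) + as.integer(coag) + as.integer(liver) +
    as.integer(renal) + as.integer(brain) + as.integer(cardio)
}
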