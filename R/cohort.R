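# Patient-record data model, delimited-file I/O, complete-case exclusion and
# summary statistics for cohort description tables.

# Canonical field set for one ICU admission. Units:
#   sodium/potassium/urea/lactate mmol/L; creatinine/bilirubin umol/L;
#   wcc/platelets 10^9/L; albumin g/L; pao2/pf_ratio kPa; map mmHg;
#   noradrenaline_dose ug/kg/min; pt_ratio dimensionless (INR-equivalent).
COHORT_NUMERIC_FIELDS <- c(
  "age", "sodium", "potassium", "urea", "lactate", "creatinine", "wcc",
  "bilirubin", "pt_ratio", "albumin", "platelets", "pao2", "pf_ratio",
  "gcs", "map", "noradrenaline_dose"
)
COHORT_FIELDS <- c(
  "patient_id", COHORT_NUMERIC_FIELDS,
  "sex", "ascites", "encephalopathy", "alcoholic_aetiology",
  "icu_outcome", "hospital_outcome"
)
ASCITES_LEVELS <- c("none", "mild", "severe")
SEX_LEVELS <- c("male", "female")
OUTCOME_LEVELS <- c("survived", "died")

#' Construct a patient cohort
#'
#' A cohort is a `data.frame` (one row per ICU admission) carrying a label and
#' free-text provenance, with the canonical clinical fields validated: unique
#' patient ids, adult ages, physiologic ranges, a non-missing ICU outcome for
#' every record. Any clinical field may be missing (`NA`); missingness is
#' never imputed.
#'
#' @param records A data.frame with (a subset of) the canonical fields;
#'   `patient_id` and `icu_outcome` are mandatory.
#' @param label Short cohort label, e.g. `"glasgow"`.
#' @param provenance Free-text metadata.
#' @return An object of class `cohort` (also a `data.frame`).
#' @export
cohort <- function(records, label = "cohort", provenance = "") {
  if (!is.data.frame(records) || nrow(records) < 1L)
    abort_validation("a cohort needs at least one record")
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(records$patient_id))
    records$patient_id <- sprintf("%s_%03d", label, seq_len(nrow(records)))
  records$patient_id <- as.character(records$patient_id)
  if (anyDuplicated(records$patient_id))
    abort_validation("patient_id must be unique within a cohort")
  if (is.null(records$icu_outcome))
    abort_validation("icu_outcome column is required")

  for (f in intersect(COHORT_NUMERIC_FIELDS, names(records)))
    records[[f]] <- as.numeric(records[[f]])
  records$icu_outcome <- check_levels(records$icu_outcome, OUTCOME_LEVELS,
                                      "icu_outcome")
  if (anyNA(records$icu_outcome))
    abort_validation("icu_outcome may not be missing for any record")
  if (!is.null(records$hospital_outcome))
    records$hospital_outcome <- check_levels(records$hospital_outcome,
                                             OUTCOME_LEVELS, "hospital_outcome")
  if (!is.null(records$sex))
    records$sex <- check_levels(records$sex, SEX_LEVELS, "sex")
  if (!is.null(records$ascites))
    records$ascites <- check_levels(records$ascites, ASCITES_LEVELS, "ascites")
  if (!is.null(records$encephalopathy)) {
    records$encephalopathy <- as.numeric(records$encephalopathy)
    bad <- !is.na(records$encephalopathy) &
      !(records$encephalopathy %in% 0:4)
    if (any(bad))
      abort_validation(sprintf(
        "encephalopathy grade must be 0-4; offending row %d value %s",
        which(bad)[1], records$encephalopathy[which(bad)[1]]))
  }
  if (!is.null(records$alcoholic_aetiology))
    records$alcoholic_aetiology <- as.logical(records$alcoholic_aetiology)

  validate_ranges(records)
  structure(records,
            label = label, provenance = provenance,
            class = c("cohort", "data.frame"))
}

check_levels <- function(x, levels, field) {
  x <- as.character(x)
  bad <- !is.na(x) & x != "" & !(x %in% levels)
  if (any(bad)) {
    i <- which(bad)[1]
    abort_validation(sprintf(
      "unknown level '%s' for %s at row %d (allowed: %s)",
      x[i], field, i, paste(levels, collapse = ", ")))
  }
  x[x == ""] <- NA_character_
  factor(x, levels = levels)
}

validate_ranges <- function(records) {
  chk <- function(cond, msg) {
    bad <- which(!is.na(cond) & cond)
    if (length(bad))
      abort_validation(sprintf("%s (first offending row %d)", msg, bad[1]))
  }
  if (!is.null(records$age)) chk(records$age < 18, "age must be >= 18")
  for (f in c("sodium", "potassium", "urea", "lactate", "creatinine", "wcc",
              "bilirubin", "pt_ratio", "albumin", "platelets", "pao2",
              "pf_ratio", "map"))
    if (!is.null(records[[f]]))
      chk(records[[f]] <= 0, sprintf("%s must be strictly positive", f))
  if (!is.null(records$noradrenaline_dose))
    chk(records$noradrenaline_dose < 0,
        "noradrenaline_dose must be non-negative")
  if (!is.null(records$gcs))
    chk(records$gcs < 3 | records$gcs > 15, "gcs must lie in [3, 15]")
  if (!is.null(records$pao2) && !is.null(records$pf_ratio))
    chk(records$pf_ratio > records$pao2 / 0.21 + 1e-6,
        "pf_ratio may not exceed pao2 / 0.21 (FiO2 cannot be below 0.21)")
  invisible(records)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort '%s'> %d records, %d fields\n",
              attr(x, "label"), nrow(x), ncol(x)))
  died <- sum(x$icu_outcome == "died")
  cat(sprintf("  ICU mortality: %d/%d (%.1f%%)\n",
              died, nrow(x), 100 * died / nrow(x)))
  if (nzchar(attr(x, "provenance") %||% ""))
    cat("  provenance:", attr(x, "provenance"), "\n")
  invisible(x)
}

#' Cohort label accessor
#' @param x A `cohort`.
#' @return The label string.
#' @export
cohort_label <- function(x) attr(x, "label")

#' Read a cohort from a delimited file
#'
#' Reads an RFC 4180 CSV (UTF-8, "." decimal separator) with one header row.
#' A schema maps file columns onto canonical fields and may declare source
#' units for known conversions; unparseable numeric cells become missing, and
#' blanks stay blank -- nothing is imputed at read time.
#'
#' @param path CSV file path.
#' @param schema Optional column mapping: either a path to a YAML/JSON file or
#'   a named list. Each entry is canonical field name -> column name, or
#'   `list(column = , unit = )` for a unit override. Supported unit
#'   conversions: `umol/L -> mmol/L` (urea), `mg/dL` for bilirubin and
#'   creatinine, `mmHg -> kPa` for oxygen tensions. `NULL` assumes canonical
#'   column names and units.
#' @return A [cohort()].
#' @export
read_cohort <- function(path, schema = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE,
                         na.strings = c("", "NA"))
  schema <- load_schema(schema)
  out <- list()
  for (field in names(schema$columns)) {
    colname <- schema$columns[[field]]
    if (!colname %in% names(raw)) next
    v <- raw[[colname]]
    if (field %in% COHORT_NUMERIC_FIELDS) {
      v <- suppressWarnings(as.numeric(v))  # unparseable cells -> missing
      v <- convert_unit(v, field, schema$units[[field]])
    }
    out[[field]] <- v
  }
  if (is.null(out$icu_outcome))
    abort_validation(sprintf(
      "input file '%s' has no ICU outcome column ('%s')",
      path, schema$columns$icu_outcome))
  cohort(as.data.frame(out, stringsAsFactors = FALSE),
         label = schema$label %||% sub("\\.[^.]*$", "", basename(path)),
         provenance = paste("read from", path))
}

load_schema <- function(schema) {
  columns <- stats::setNames(as.list(COHORT_FIELDS), COHORT_FIELDS)
  units <- list()
  label <- NULL
  if (is.character(schema) && length(schema) == 1L) {
    schema <- if (grepl("\\.json$", schema)) jsonlite::read_json(schema)
              else yaml::read_yaml(schema)
  }
  if (!is.null(schema)) {
    label <- schema$label
    fields <- schema$fields %||% schema
    fields$label <- NULL
    for (field in names(fields)) {
      if (!field %in% COHORT_FIELDS)
        abort_validation(sprintf("schema names unknown field '%s'", field))
      entry <- fields[[field]]
      if (is.list(entry)) {
        columns[[field]] <- entry$column %||% field
        if (!is.null(entry$unit)) units[[field]] <- entry$unit
      } else columns[[field]] <- entry
    }
  }
  list(columns = columns, units = units, label = label)
}

convert_unit <- function(v, field, unit) {
  if (is.null(unit)) return(v)
  key <- paste(field, tolower(unit))
  switch(key,
    "urea umol/l" = v / 1000,
    "urea mmol/l" = v,
    "bilirubin mg/dl" = v * BILIRUBIN_UMOL_PER_MGDL,
    "bilirubin umol/l" = v,
    "creatinine mg/dl" = v * CREATININE_UMOL_PER_MGDL,
    "creatinine umol/l" = v,
    "pao2 mmhg" = v / KPA_TO_MMHG,
    "pao2 kpa" = v,
    "pf_ratio mmhg" = v / KPA_TO_MMHG,
    "pf_ratio kpa" = v,
    abort_validation(sprintf("no unit conversion for %s from '%s'",
                             field, unit)))
}

#' Write a cohort to CSV
#'
#' Missing values are written as empty cells, so a read/write/read cycle
#' round-trips numeric values exactly at the printed precision.
#'
#' @param x A `cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Complete-case exclusion
#'
#' Drops every record missing any of the required fields, returning the
#' retained cohort and the excluded patient ids. Record order is preserved
#' and the two outputs partition the input; the operation is idempotent.
#'
#' @param x A `cohort`.
#' @param required_fields Character vector of field names that must be
#'   non-missing (non-empty).
#' @return A list with elements `cohort` (retained records; may have zero
#'   rows) and `excluded_ids` (character).
#' @export
exclude_incomplete <- function(x, required_fields) {
  if (length(required_fields) == 0L)
    abort_validation("required_fields must be non-empty")
  missing_fields <- setdiff(required_fields, names(x))
  if (length(missing_fields))
    abort_validation(paste("unknown field(s):",
                           paste(missing_fields, collapse = ", ")))
  keep <- rep(TRUE, nrow(x))
  for (f in required_fields) keep <- keep & !is.na(x[[f]])
  retained <- as.data.frame(x)[keep, , drop = FALSE]
  retained_cohort <- structure(retained,
                               label = attr(x, "label"),
                               provenance = attr(x, "provenance"),
                               class = class(x))
  list(cohort = retained_cohort,
       excluded_ids = x$patient_id[!keep])
}

#' Summarize one cohort field
#'
#' Produces the descriptive statistic used in cohort characteristic tables:
#' mean with range, median with interquartile range (linear interpolation
#' between closest ranks, i.e. quantile type 7), or count with percent.
#' Percentages use the full cohort size as denominator, including records
#' missing other fields.
#'
#' @param x A `cohort` (or data.frame).
#' @param field Field name.
#' @param kind One of `"mean_range"`, `"median_iqr"`, `"count_percent"`.
#' @param level For `count_percent`: the level(s) counted as positive; for a
#'   logical field the default counts `TRUE`.
#' @return A list of class `field_summary` with the statistics, `n_nonmissing`,
#'   `available` flag and a `formatted` display string.
#' @export
summarize_field <- function(x, field,
                            kind = c("mean_range", "median_iqr",
                                     "count_percent"),
                            level = NULL) {
  kind <- match.arg(kind)
  if (!field %in% names(x))
    abort_validation(sprintf("unknown field '%s'", field))
  v <- x[[field]]
  n_total <- nrow(x)
  v_ok <- v[!is.na(v)]
  base <- list(field = field, kind = kind, n = n_total,
               n_nonmissing = length(v_ok))
  if (length(v_ok) == 0L) {
    return(structure(c(base, list(available = FALSE,
                                  formatted = "unavailable")),
                     class = "field_summary"))
  }
  out <- switch(kind,
    mean_range = {
      m <- mean(v_ok)
      list(mean = m, min = min(v_ok), max = max(v_ok),
           formatted = sprintf("%.1f (%.1f-%.1f)", m, min(v_ok), max(v_ok)))
    },
    median_iqr = {
      q <- stats::quantile(v_ok, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      list(median = q[2], q25 = q[1], q75 = q[3],
           formatted = sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3]))
    },
    count_percent = {
      pos <- if (is.logical(v_ok)) {
        if (is.null(level)) v_ok else v_ok %in% as.logical(level)
      } else as.character(v_ok) %in% as.character(level)
      cnt <- sum(pos)
      pct <- 100 * cnt / n_total
      list(count = cnt, percent = pct,
           formatted = sprintf("%d (%.1f%%)", cnt, pct))
    })
  structure(c(base, list(available = TRUE), out), class = "field_summary")
}

#' @export
print.field_summary <- function(x, ...) {
  cat(sprintf("%s [%s]: %s  (n=%d, non-missing=%d)\n",
              x$field, x$kind, x$formatted, x$n, x$n_nonmissing))
  invisible(x)
}
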