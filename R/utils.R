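# Internal helpers shared across modules.

# Unit conversion constants used by score definitions and schema overrides.
KPA_TO_MMHG <- 7.50062
BILIRUBIN_UMOL_PER_MGDL <- 17.1
CREATININE_UMOL_PER_MGDL <- 88.4

abort_validation <- function(msg, call. = FALSE) {
  cond <- structure(
    class = c("ctpl_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Format a p-value the way clinical tables print it
#'
#' Values below the threshold are rendered as `"<0.001"`; larger values are
#' rounded to `digits` significant figures.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param threshold Reporting floor (default 0.001).
#' @param digits Significant digits for values at or above the floor.
#' @return Character vector.
#' @export
#' @examples
#' format_p(c(0.0004, 0.023, 0.55))
format_p <- function(p, threshold = 0.001, digits = 2) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < threshold, paste0("<", format(threshold)),
                formatC(signif(p, digits), format = "fg")))
}

# Two-sided p from a z statistic.
p_from_z <- function(z) 2 * stats::pnorm(-abs(z))
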