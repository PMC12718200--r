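# Thermochemical kilojoule-per-kilocalorie conversion factor.
KJ_PER_KCAL <- 4.184

#' Convert kilojoules to kilocalories
#'
#' Uses the thermochemical factor 4.184 kJ/kcal throughout the package, the
#' convention under which the energy-plausibility bounds 2568 and 17031 kJ/d
#' correspond to roughly 614 and 4070 kcal/d.
#'
#' @param kj Energy in kJ.
#' @return Energy in kcal.
#' @export
#' @examples
#' kj_to_kcal(2568)
kj_to_kcal <- function(kj) kj / KJ_PER_KCAL

#' Render a count with its percentage
#'
#' Formats a count as `"n (pct)"` with the percentage at one decimal place,
#' the display convention used in descriptive baseline tables
#' (e.g. `format_count_pct(61, 150)` is `"61 (40.7)"`).
#'
#' @param n Count.
#' @param total Denominator.
#' @param digits Decimal places for the percentage.
#' @return Character vector.
#' @export
format_count_pct <- function(n, total, digits = 1) {
  pct <- round(100 * n / total, digits)
  sprintf("%d (%s)", as.integer(n), formatC(pct, format = "f", digits = digits))
}

# Internal: check that required columns exist in a data frame.
check_columns <- function(data, cols, fn) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s(): missing required column(s): %s",
                  fn, paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

# Internal: validate integer item responses within [lo, hi]; NA allowed.
check_item_range <- function(mat, lo, hi, instrument) {
  vals <- mat[!is.na(mat)]
  if (length(vals) > 0 && (any(vals < lo) || any(vals > hi))) {
    abort(sprintf("%s item responses must lie in {%d..%d}; found values outside that range",
                  instrument, lo, hi))
  }
  invisible(TRUE)
}

# Internal: id column of a cohort (falls back to row number).
record_ids <- function(data) {
  if ("id" %in% names(data)) data$id else as.character(seq_len(nrow(data)))
}
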