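#' Default component cut-points for the WCRF/AICR and EHLI indices
#'
#' Threshold tables for the two fixed-cut-point indices (the Mediterranean
#' diet score uses cohort medians and carries only its ethanol window here).
#' Values follow the standardized WCRF/AICR scoring conventions and common
#' healthy-lifestyle-index conventions: full compliance scores 1, partial
#' 0.5, non-compliance 0. All thresholds are plain scalars so the whole
#' configuration serializes losslessly to JSON and alternative threshold
#' tables can be dropped in without code change.
#'
#' Units: intakes g/d (meat thresholds g/wk), dietary energy density kcal/g,
#' activity moderate-equivalent min/wk, alcohol g ethanol/d, BMI kg/m2.
#'
#' @return A list of class `dl_cutpoints`.
#' @export
default_cutpoints <- function() {
  structure(list(
    version = "dietlife-default-1",
    mds = list(alcohol_lower = 5, alcohol_upper = 25),
    wcrf = list(
      bmi_full_min = 18.5, bmi_full_max = 25, bmi_partial_max = 30,
      activity_full = 150, activity_partial = 75,
      density_full = 1.25, density_partial = 1.75,
      drinks_full = 0, drinks_partial = 250,
      fv_full = 400, fv_partial = 200, fiber_full = 30, fiber_partial = 15,
      red_wk_max = 500, processed_wk_full = 21, processed_wk_partial = 100,
      alcohol_full = 0, alcohol_partial = 10
    ),
    ehli = list(
      alcohol_full = 0, alcohol_partial = 10,
      activity_full = 150, activity_partial = 75,
      bmi_full_min = 18.5, bmi_full_max = 25, bmi_partial_max = 30,
      fv_full = 400, fv_partial = 200,
      drinks_full = 0, drinks_partial = 250,
      meat_wk_full = 300, meat_wk_partial = 500,
      grains_full = 90, grains_partial = 30,
      dairy_full = 500, dairy_partial = 700
    )
  ), class = "dl_cutpoints")
}

validate_cutpoints <- function(cp) {
  for (section in c("mds", "wcrf", "ehli")) {
    if (is.null(cp[[section]])) {
      abort(sprintf("cut-point config is missing the '%s' section", section))
    }
  }
  w <- cp$wcrf
  e <- cp$ehli
  ordered <- c(
    cp$mds$alcohol_lower < cp$mds$alcohol_upper,
    w$bmi_full_min < w$bmi_full_max, w$bmi_full_max <= w$bmi_partial_max,
    w$activity_partial < w$activity_full,
    w$density_full < w$density_partial,
    w$drinks_full <= w$drinks_partial,
    w$fv_partial < w$fv_full, w$fiber_partial < w$fiber_full,
    w$processed_wk_full < w$processed_wk_partial,
    w$alcohol_full <= w$alcohol_partial,
    e$alcohol_full <= e$alcohol_partial,
    e$activity_partial < e$activity_full,
    e$fv_partial < e$fv_full,
    e$meat_wk_full < e$meat_wk_partial,
    e$grains_partial < e$grains_full,
    e$dairy_full < e$dairy_partial
  )
  if (!all(ordered)) abort("cut-point thresholds are not correctly ordered")
  invisible(cp)
}

#' Write cut-points to JSON
#' @param cutpoints A `dl_cutpoints` list.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cutpoints <- function(cutpoints, path) {
  jsonlite::write_json(unclass(cutpoints), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read cut-points from JSON
#' @param path File path written by [write_cutpoints()].
#' @return A validated `dl_cutpoints` list.
#' @export
read_cutpoints <- function(path) {
  cp <- structure(jsonlite::read_json(path, simplifyVector = TRUE),
                  class = "dl_cutpoints")
  validate_cutpoints(cp)
  cp
}
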