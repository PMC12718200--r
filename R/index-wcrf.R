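# Three-level scorer: 1 if `full`, else 0.5 if `partial`, else 0. NA in.
score3 <- function(full, partial) {
  dplyr::case_when(is.na(full) | is.na(partial) ~ NA_real_,
                   full ~ 1, partial ~ 0.5, TRUE ~ 0)
}

score_bmi_component <- function(bmi, cp) {
  score3(bmi >= cp$bmi_full_min & bmi < cp$bmi_full_max,
         bmi >= cp$bmi_full_min & bmi < cp$bmi_partial_max)
}

score_activity_component <- function(pa, cp) {
  score3(pa >= cp$activity_full, pa >= cp$activity_partial)
}

#' Compute the modified WCRF/AICR adherence score
#'
#' Six retained cancer-prevention recommendations, each scored 1 (low-risk
#' behaviour), 0.5 (moderate risk) or 0 (high risk); the salt, supplement
#' and breastfeeding recommendations are not scored, so totals range 0-6.
#' Components: healthy BMI; physical activity (moderate-equivalent min/wk);
#' limiting energy-dense food (dietary energy density, kcal/g) and sugary
#' drinks; plant foods (fruit, nuts, vegetables and legumes, plus fiber);
#' limiting red and processed meat (g/wk); limiting alcohol (full
#' compliance at 0 g ethanol/d). Legumes count inside the fruit-and-
#' vegetable category for this index.
#'
#' Records missing BMI or physical activity are flagged `wcrf_unscoreable`
#' with a missing total rather than silently dropped, so the diet-and-
#' lifestyle analytic sample (where both are observed) is the intended
#' input.
#'
#' @param data Analytic sample with `bmi` (or `height_cm` + `weight_kg`),
#'   `physical_activity`, `energy_density`, `sugary_drinks`, `fruit_nuts`,
#'   `vegetables`, `legumes`, `fiber`, `red_meat`, `processed_meat`,
#'   `alcohol`.
#' @param cutpoints A [default_cutpoints()] list.
#' @return Tibble of `wcrf_*` component scores, `wcrf_total`, and
#'   `wcrf_unscoreable`.
#' @export
compute_wcrf <- function(data, cutpoints = default_cutpoints()) {
  validate_cutpoints(cutpoints)
  cp <- cutpoints$wcrf
  if (!"bmi" %in% names(data)) {
    check_columns(data, c("height_cm", "weight_kg"), "compute_wcrf")
    data$bmi <- data$weight_kg / (data$height_cm / 100)^2
  }
  check_columns(data, c("bmi", "physical_activity", "energy_density",
                        "sugary_drinks", "fruit_nuts", "vegetables", "legumes",
                        "fiber", "red_meat", "processed_meat", "alcohol"),
                "compute_wcrf")

  fv <- data$fruit_nuts + data$vegetables + data$legumes
  red_wk <- data$red_meat * 7
  proc_wk <- data$processed_meat * 7

  scores <- tibble::tibble(
    id = record_ids(data),
    wcrf_bmi = score_bmi_component(data$bmi, cp),
    wcrf_activity = score_activity_component(data$physical_activity, cp),
    wcrf_energy_dense = score3(
      data$energy_density < cp$density_full & data$sugary_drinks <= cp$drinks_full,
      data$energy_density < cp$density_partial & data$sugary_drinks <= cp$drinks_partial),
    wcrf_plant = score3(fv >= cp$fv_full & data$fiber >= cp$fiber_full,
                        fv >= cp$fv_partial | data$fiber >= cp$fiber_partial),
    wcrf_meat = score3(red_wk < cp$red_wk_max & proc_wk < cp$processed_wk_full,
                       red_wk < cp$red_wk_max & proc_wk < cp$processed_wk_partial),
    wcrf_alcohol = score3(data$alcohol <= cp$alcohol_full,
                          data$alcohol <= cp$alcohol_partial)
  )
  comp <- dplyr::select(scores, dplyr::starts_with("wcrf_"))
  scores$wcrf_total <- rowSums(comp)
  scores$wcrf_unscoreable <- is.na(scores$wcrf_total)
  scores
}
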