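#' Compute the Extended Healthy Lifestyle Index
#'
#' Nine components, each scored 1 (full compliance), 0.5 (partial) or 0
#' (non-compliance); totals range 0-9. The five original healthy-lifestyle
#' components are smoking status (never / former / current), alcohol,
#' physical activity, BMI, and fruit-and-vegetable intake; the four added
#' dietary components are weight-gain-promoting (sugary) drinks, red and
#' processed meat combined, unprocessed grains and/or legumes (legumes
#' count inside the whole-grain category for this index), and dairy
#' products.
#'
#' Records missing smoking, BMI or physical activity are flagged
#' `ehli_unscoreable` with a missing total rather than dropped.
#'
#' @param data Analytic sample with `smoking`, `alcohol`,
#'   `physical_activity`, `bmi` (or `height_cm` + `weight_kg`),
#'   `fruit_nuts`, `vegetables`, `sugary_drinks`, `red_meat`,
#'   `processed_meat`, `whole_grains`, `legumes`, `dairy`.
#' @param cutpoints A [default_cutpoints()] list.
#' @return Tibble of `ehli_*` component scores, `ehli_total`, and
#'   `ehli_unscoreable`.
#' @export
compute_ehli <- function(data, cutpoints = default_cutpoints()) {
  validate_cutpoints(cutpoints)
  cp <- cutpoints$ehli
  if (!"bmi" %in% names(data)) {
    check_columns(data, c("height_cm", "weight_kg"), "compute_ehli")
    data$bmi <- data$weight_kg / (data$height_cm / 100)^2
  }
  check_columns(data, c("smoking", "alcohol", "physical_activity", "bmi",
                        "fruit_nuts", "vegetables", "sugary_drinks",
                        "red_meat", "processed_meat", "whole_grains",
                        "legumes", "dairy"),
                "compute_ehli")

  fv <- data$fruit_nuts + data$vegetables
  meat_wk <- (data$red_meat + data$processed_meat) * 7
  grains <- data$whole_grains + data$legumes

  scores <- tibble::tibble(
    id = record_ids(data),
    ehli_smoking = dplyr::case_when(is.na(data$smoking) ~ NA_real_,
                                    data$smoking == "never" ~ 1,
                                    data$smoking == "former" ~ 0.5,
                                    TRUE ~ 0),
    ehli_alcohol = score3(data$alcohol <= cp$alcohol_full,
                          data$alcohol <= cp$alcohol_partial),
    ehli_activity = score_activity_component(data$physical_activity, cp),
    ehli_bmi = score_bmi_component(data$bmi, cp),
    ehli_fruit_veg = score3(fv >= cp$fv_full, fv >= cp$fv_partial),
    ehli_sugary_drinks = score3(data$sugary_drinks <= cp$drinks_full,
                                data$sugary_drinks <= cp$drinks_partial),
    ehli_meat = score3(meat_wk < cp$meat_wk_full, meat_wk < cp$meat_wk_partial),
    ehli_grains_legumes = score3(grains >= cp$grains_full,
                                 grains >= cp$grains_partial),
    ehli_dairy = score3(data$dairy <= cp$dairy_full, data$dairy <= cp$dairy_partial)
  )
  comp <- dplyr::select(scores, dplyr::starts_with("ehli_"))
  scores$ehli_total <- rowSums(comp)
  scores$ehli_unscoreable <- is.na(scores$ehli_total)
  scores
}

#' Per-component adherence flags for an index score table
#'
#' A component is adherent when it attains its maximum score (1 for every
#' component of all three indices).
#'
#' @param scores Output of [compute_mds()], [compute_wcrf()] or
#'   [compute_ehli()].
#' @return Tibble of logical flags, one column per component.
#' @export
adherence_flags <- function(scores) {
  comp <- dplyr::select(scores, dplyr::matches("^(mds|wcrf|ehli)_"),
                        -dplyr::matches("_(total|unscoreable)$"))
  dplyr::bind_cols(tibble::tibble(id = scores$id),
                   dplyr::mutate(comp, dplyr::across(dplyr::everything(), ~ .x == 1)))
}
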