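#' Homeostatic Model Assessment of Insulin Resistance
#'
#' `HOMA-IR = fasting glucose (mmol/L) x fasting insulin (as recorded) /
#' 22.5`. Missing inputs propagate to a missing result (the record is
#' retained); non-positive inputs are an error naming the offending
#' records.
#'
#' @param glucose Fasting glucose, mmol/L.
#' @param insulin Fasting insulin, as recorded.
#' @param ids Optional record identifiers used in error messages.
#' @return Numeric vector of HOMA-IR values.
#' @export
#' @examples
#' compute_homa_ir(4.5, 5) # 1
compute_homa_ir <- function(glucose, insulin, ids = NULL) {
  ids <- ids %||% as.character(seq_along(glucose))
  bad <- which((!is.na(glucose) & glucose <= 0) | (!is.na(insulin) & insulin <= 0))
  if (length(bad) > 0) {
    abort(sprintf("compute_homa_ir(): nonpositive glucose or insulin for record(s): %s",
                  paste(ids[bad], collapse = ", ")))
  }
  glucose * insulin / 22.5
}

#' Derive anthropometric indices
#'
#' `BMI = weight / (height/100)^2` and `waist-to-hip ratio = waist / hip`.
#'
#' @param height_cm,weight_kg,waist_cm,hip_cm Positive measurements;
#'   missing values propagate.
#' @return Tibble with `bmi` and `waist_hip_ratio`.
#' @export
#' @examples
#' derive_anthropometry(160, 76.8, 129.7, 144.9)
derive_anthropometry <- function(height_cm, weight_kg, waist_cm, hip_cm) {
  nonpos <- function(x) any(!is.na(x) & x <= 0)
  if (nonpos(height_cm) || nonpos(weight_kg) || nonpos(waist_cm) || nonpos(hip_cm)) {
    abort("derive_anthropometry(): all anthropometric inputs must be strictly positive")
  }
  tibble::tibble(bmi = weight_kg / (height_cm / 100)^2,
                 waist_hip_ratio = waist_cm / hip_cm)
}

#' Derive the full outcome panel
#'
#' Assembles the seventeen modeled outcomes for a cohort: the four glycemic
#' parameters (HbA1c, fasting insulin, fasting glucose, HOMA-IR), four
#' anthropometric outcomes (BMI recomputed from measured height and weight,
#' waist, hip, waist-to-hip ratio), the six FACIT quality-of-life scores and
#' the three HADS scores with severity categories.
#'
#' @param data Cohort tibble with anthropometry, glycemic measurements and
#'   questionnaire item columns.
#' @param facit_key FACIT scoring key; see [default_facit_key()].
#' @return Tibble with `id` and one column per outcome plus HADS severity
#'   categories.
#' @export
score_outcomes <- function(data, facit_key = default_facit_key()) {
  check_columns(data, c("height_cm", "weight_kg", "waist_cm", "hip_cm",
                        "hba1c", "fasting_glucose", "fasting_insulin"),
                "score_outcomes")
  anthro <- derive_anthropometry(data$height_cm, data$weight_kg,
                                 data$waist_cm, data$hip_cm)
  out <- tibble::tibble(
    id = record_ids(data),
    hba1c = data$hba1c,
    fasting_insulin = data$fasting_insulin,
    fasting_glucose = data$fasting_glucose,
    homa_ir = compute_homa_ir(data$fasting_glucose, data$fasting_insulin,
                              record_ids(data)),
    bmi = anthro$bmi,
    waist_cm = data$waist_cm,
    hip_cm = data$hip_cm,
    waist_hip_ratio = anthro$waist_hip_ratio
  )
  dplyr::bind_cols(out,
                   dplyr::select(score_facit(data, facit_key), -"id"),
                   dplyr::select(score_hads(data), -"id"))
}
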