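# Minimal one-or-more-row participant table with sensible defaults; any
# column can be overridden with a scalar or length-n vector.
toy_participants <- function(n = 1, ...) {
  defaults <- tibble::tibble(
    fruit_nuts = 150, vegetables = 200, legumes = 20, cereals = 180,
    whole_grains = 40, refined_grains = 120, fish_seafood = 30, dairy = 300,
    red_meat = 80, processed_meat = 25, sugary_drinks = 100,
    energy_density = 1.6, total_energy = 8000, mufa = 30, sfa = 32,
    fiber = 20, alcohol = 0, physical_activity = 0, smoking = "never",
    bmi = 45, height_cm = 160, weight_kg = 115.2, waist_cm = 130,
    hip_cm = 145, age = 55, education = "high school or less",
    marital_status = "partner", comorbidities = "0",
    hba1c = 5.8, fasting_glucose = 5.9, fasting_insulin = 19
  )
  out <- defaults[rep(1, n), ]
  for (nm in names(list(...))) out[[nm]] <- list(...)[[nm]]
  out$id <- sprintf("T%03d", seq_len(n))
  out
}

# One row of the 43 raw FACIT item responses whose *scored* value (after
# reverse mapping) equals `scored` for every item.
facit_raw_row <- function(scored = 4) {
  key <- default_facit_key()
  items <- unlist(key$domains, use.names = FALSE)
  vals <- as.list(setNames(rep(scored, length(items)), items))
  for (nm in key$reverse) vals[[nm]] <- 4 - scored
  tibble::as_tibble(vals)
}

# One row of the 14 HADS item responses, all equal to `value`.
hads_row <- function(value = 0) {
  items <- c(paste0("hads_a", 1:7), paste0("hads_d", 1:7))
  tibble::as_tibble(as.list(setNames(rep(value, length(items)), items)))
}

# A fully observed scored analytic dataset for association models, with a
# known linear relationship available through plant_effect().
scored_analysis_data <- function(n = 150, seed = 42) {
  cfg <- cohort_config(n_participants = n, seed = seed,
                       missingness = c(none = 0), item_missingness = 0)
  cohort <- generate_cohort(cfg)
  mds <- compute_mds(cohort)
  wcrf <- compute_wcrf(cohort)
  ehli <- compute_ehli(cohort)
  outcomes <- score_outcomes(cohort)
  new_cols <- c("id", setdiff(names(outcomes), names(cohort)))
  cohort |>
    dplyr::left_join(dplyr::select(mds, "id", "mds_total"), by = "id") |>
    dplyr::left_join(dplyr::select(wcrf, "id", "wcrf_total"), by = "id") |>
    dplyr::left_join(dplyr::select(ehli, "id", "ehli_total"), by = "id") |>
    dplyr::left_join(outcomes[new_cols], by = "id")
}
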