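#' Default marginal distributions for the synthetic cohort
#'
#' One spec per generated variable. Continuous variables are (truncated)
#' normal or lognormal, chosen to match the baseline summaries the cohort
#' emulates: a severely obese, mostly inactive, mostly post-menopausal
#' population of females (BMI normal mean 47.5, SD 9.3, truncated at 30;
#' 66% aged 50 or over; lognormal glycemic markers matching the printed
#' medians and IQRs). Intakes are lognormal in g/d; total energy is
#' lognormal with parameters whose +/- 3 SD log-range reproduces the
#' 2568-17031 kJ/d plausibility window. Fasting insulin reproduces the
#' printed numeric scale (median 19.0) as recorded, without asserting unit
#' correctness.
#'
#' Supported families: `"normal"` (optional `lower`/`upper` truncation),
#' `"lognormal"` (`meanlog`, `sdlog`), `"zero_inflated_lognormal"`
#' (`p_zero`, then lognormal), `"categorical"` (`levels`, `probs`).
#'
#' @return Named list of marginal specs.
#' @export
default_marginals <- function() {
  list(
    age = list(family = "normal", mean = 53.5, sd = 8.5, lower = 18),
    height_cm = list(family = "normal", mean = 161, sd = 6.5, lower = 130),
    bmi = list(family = "normal", mean = 47.5, sd = 9.3, lower = 30),
    waist_cm = list(family = "normal", mean = 129.7, sd = 17.0, lower = 60),
    hip_cm = list(family = "normal", mean = 144.9, sd = 18.9, lower = 70),
    hba1c = list(family = "lognormal", meanlog = log(5.8), sdlog = 0.128),
    fasting_glucose = list(family = "lognormal", meanlog = log(5.9), sdlog = 0.238),
    fasting_insulin = list(family = "lognormal", meanlog = log(19), sdlog = 0.747),
    total_energy = list(family = "lognormal", meanlog = 8.797, sdlog = 0.315),
    fruit_nuts = list(family = "lognormal", meanlog = log(150), sdlog = 0.6),
    vegetables = list(family = "lognormal", meanlog = log(200), sdlog = 0.5),
    legumes = list(family = "lognormal", meanlog = log(20), sdlog = 0.9),
    cereals = list(family = "lognormal", meanlog = log(180), sdlog = 0.5),
    whole_grains = list(family = "lognormal", meanlog = log(40), sdlog = 0.8),
    refined_grains = list(family = "lognormal", meanlog = log(120), sdlog = 0.6),
    fish_seafood = list(family = "lognormal", meanlog = log(30), sdlog = 0.8),
    dairy = list(family = "lognormal", meanlog = log(300), sdlog = 0.6),
    red_meat = list(family = "lognormal", meanlog = log(80), sdlog = 0.6),
    processed_meat = list(family = "lognormal", meanlog = log(25), sdlog = 0.9),
    sugary_drinks = list(family = "lognormal", meanlog = log(100), sdlog = 1.0),
    energy_density = list(family = "normal", mean = 1.6, sd = 0.35, lower = 0.5),
    mufa = list(family = "lognormal", meanlog = log(30), sdlog = 0.4),
    sfa = list(family = "lognormal", meanlog = log(32), sdlog = 0.4),
    fiber = list(family = "lognormal", meanlog = log(20), sdlog = 0.4),
    alcohol = list(family = "zero_inflated_lognormal", p_zero = 0.70,
                   meanlog = log(8), sdlog = 0.8),
    physical_activity = list(family = "zero_inflated_lognormal", p_zero = 0.776,
                             meanlog = log(120), sdlog = 0.7),
    race = list(family = "categorical",
                levels = c("white", "non-white/other"), probs = c(0.687, 0.313)),
    education = list(family = "categorical",
                     levels = c("high school or less", "TAFE, diploma or university"),
                     probs = c(0.537, 0.463)),
    income = list(family = "categorical",
                  levels = c("low", "middle", "high"),
                  probs = c(0.245, 0.399, 0.356)),
    marital_status = list(family = "categorical",
                          levels = c("partner", "no partner"),
                          probs = c(0.591, 0.409)),
    menopausal_status = list(family = "categorical",
                             levels = c("pre", "post"), probs = c(0.407, 0.593)),
    smoking = list(family = "categorical",
                   levels = c("never", "former", "current"),
                   probs = c(0.547, 0.360, 0.093)),
    family_history = list(family = "categorical",
                          levels = c("no", "yes"), probs = c(0.246, 0.754)),
    diabetes = list(family = "categorical",
                    levels = c("no", "yes"), probs = c(0.693, 0.307)),
    comorbidities = list(family = "categorical",
                         levels = c("0", "1+"), probs = c(0.347, 0.653))
  )
}

#' Default rank-correlation blocks for the synthetic cohort
#'
#' Correlation targets are induced through a Gaussian copula on blocks of
#' continuous variables with exchangeable correlation: modest positive
#' correlation among intake variables, stronger within anthropometry and
#' within the glycemic panel. Variables outside every block are independent.
#'
#' @return List of blocks, each `list(vars =, rho =)`.
#' @export
default_correlations <- function() {
  list(
    list(vars = c("total_energy", "fruit_nuts", "vegetables", "legumes",
                  "cereals", "whole_grains", "refined_grains", "fish_seafood",
                  "dairy", "red_meat", "processed_meat", "sugary_drinks",
                  "mufa", "sfa", "fiber"), rho = 0.2),
    list(vars = c("bmi", "waist_cm", "hip_cm"), rho = 0.5),
    list(vars = c("fasting_glucose", "fasting_insulin", "hba1c"), rho = 0.4)
  )
}

#' Default per-variable missingness rates
#'
#' Small missingness rates mirroring the structure of the emulated baseline
#' table (a handful of missing education/marital entries, a few missing
#' activity measurements, more missing family-history responses).
#'
#' @return Named numeric vector of proportions in `[0, 1]`.
#' @export
default_missingness <- function() {
  c(education = 0.007, marital_status = 0.007, income = 0.047,
    family_history = 0.107, physical_activity = 0.02)
}

#' Build a synthetic-cohort configuration
#'
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including the seed.
#' @param marginals Named list of per-variable distribution specs; see
#'   [default_marginals()].
#' @param correlations Copula correlation blocks; see [default_correlations()].
#' @param missingness Named per-variable missingness proportions in `[0, 1]`.
#' @param facit_domain_means Target mean domain totals for the five FACIT
#'   quality-of-life domains (physical, social, emotional, functional,
#'   additional), on the scored scale.
#' @param hads_domain_means Target mean subscale totals for HADS anxiety and
#'   depression.
#' @param item_missingness Proportion of questionnaire items set missing, to
#'   exercise the proration rules downstream.
#'
#' @return A list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_participants = 50, seed = 1)
#' cohort <- generate_cohort(cfg)
cohort_config <- function(n_participants = 157, seed = 1L,
                          marginals = default_marginals(),
                          correlations = default_correlations(),
                          missingness = default_missingness(),
                          facit_domain_means = c(physical = 20.7, social = 21.0,
                                                 emotional = 16.8, functional = 16.3,
                                                 additional = 46.4),
                          hads_domain_means = c(anxiety = 12.8, depression = 14.7),
                          item_missingness = 0.02) {
  cfg <- structure(
    list(n_participants = as.integer(n_participants), seed = as.integer(seed),
         marginals = marginals, correlations = correlations,
         missingness = missingness, facit_domain_means = facit_domain_means,
         hads_domain_means = hads_domain_means,
         item_missingness = item_missingness),
    class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (is.na(cfg$n_participants) || cfg$n_participants < 1) {
    abort("cohort_config: n_participants must be >= 1")
  }
  if (any(cfg$missingness < 0 | cfg$missingness > 1)) {
    abort("cohort_config: all missingness rates must lie in [0, 1]")
  }
  known <- c("normal", "lognormal", "zero_inflated_lognormal", "categorical")
  for (nm in names(cfg$marginals)) {
    spec <- cfg$marginals[[nm]]
    if (is.null(spec$family) || !spec$family %in% known) {
      abort(sprintf("cohort_config: invalid distribution family '%s' for variable '%s'",
                    spec$family %||% "<missing>", nm))
    }
    if (spec$family == "normal") {
      lo <- spec$lower %||% -Inf
      hi <- spec$upper %||% Inf
      plo <- pnorm(lo, spec$mean, spec$sd)
      phi <- pnorm(hi, spec$mean, spec$sd)
      if (!(phi > plo)) {
        abort(sprintf("cohort_config: infeasible truncation for variable '%s'", nm))
      }
    }
    if (spec$family == "categorical" &&
        length(spec$levels) != length(spec$probs)) {
      abort(sprintf("cohort_config: levels/probs length mismatch for variable '%s'", nm))
    }
  }
  if (cfg$item_missingness < 0 || cfg$item_missingness > 1) {
    abort("cohort_config: item_missingness must lie in [0, 1]")
  }
  invisible(cfg)
}
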