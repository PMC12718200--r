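#' Names of the seventeen modeled outcomes
#'
#' Four glycemic outcomes (modeled on the log scale), four anthropometric
#' outcomes, six FACIT quality-of-life scores, and three HADS scores.
#'
#' @return Character vector of outcome column names.
#' @export
outcome_names <- function() {
  c("hba1c", "fasting_insulin", "fasting_glucose", "homa_ir",
    "bmi", "waist_cm", "hip_cm", "waist_hip_ratio",
    "facit_physical", "facit_social", "facit_emotional", "facit_functional",
    "facit_additional", "facit_general",
    "hads_anxiety", "hads_depression", "hads_overall")
}

#' Outcomes modeled on the natural-log scale
#'
#' The four glycemic parameters whose regression residuals are non-normal on
#' the raw scale and which are therefore log-transformed before modeling,
#' with estimates exponentiated back.
#'
#' @return Character vector.
#' @export
log_outcome_names <- function() {
  c("hba1c", "fasting_insulin", "fasting_glucose", "homa_ir")
}

#' Plant a known exposure-outcome effect in a cohort
#'
#' Overwrites one outcome column as a linear function of the z-standardized
#' exposure plus optional covariate terms and Gaussian noise:
#' `outcome = intercept + beta_per_sd * z(exposure) + covariates + noise`.
#' For glycemic outcomes (see [log_outcome_names()]) the linear predictor is
#' built on the log scale and exponentiated, the generative twin of the
#' fitted log-linear models, so `beta_per_sd` is a log-scale coefficient
#' there. With `noise_sd = 0`, refitting the matching model recovers
#' `beta_per_sd` exactly up to numerical tolerance.
#'
#' @param data Cohort tibble containing `exposure` and any covariate columns.
#' @param exposure Name of the exposure column (an index total).
#' @param outcome Name of the outcome to overwrite; must be one of
#'   [outcome_names()].
#' @param beta_per_sd Effect per 1 SD of exposure on the outcome's modeling
#'   scale.
#' @param covariate_effects Optional named numeric vector mapping numeric
#'   covariate columns to coefficients.
#' @param noise_sd Residual SD (>= 0) on the modeling scale.
#' @param intercept Intercept on the modeling scale; defaults to 0 (log
#'   outcomes then center at 1 on the raw scale unless specified).
#' @param log_scale Whether to build the outcome on the log scale; defaults
#'   to `outcome %in% log_outcome_names()`.
#' @param seed Optional seed for the noise draw.
#' @return `data` with the outcome column overwritten.
#' @export
plant_effect <- function(data, exposure, outcome, beta_per_sd,
                         covariate_effects = NULL, noise_sd = 0,
                         intercept = 0,
                         log_scale = outcome %in% log_outcome_names(),
                         seed = NULL) {
  if (!outcome %in% outcome_names()) {
    abort(sprintf("plant_effect(): unknown outcome '%s'; valid outcomes: %s",
                  outcome, paste(outcome_names(), collapse = ", ")))
  }
  check_columns(data, c(exposure, names(covariate_effects)), "plant_effect")
  if (noise_sd < 0) abort("plant_effect(): noise_sd must be >= 0")
  z <- standardize_exposure(data[[exposure]])
  lp <- intercept + beta_per_sd * z
  for (nm in names(covariate_effects)) {
    lp <- lp + covariate_effects[[nm]] * data[[nm]]
  }
  noise <- if (is.null(seed)) {
    rnorm(nrow(data), 0, noise_sd)
  } else {
    withr::with_seed(seed, rnorm(nrow(data), 0, noise_sd))
  }
  lp <- lp + noise
  data[[outcome]] <- if (log_scale) exp(lp) else lp
  data
}

#' Build a cohort fixture with planted exclusion flags
#'
#' Generates a clean cohort (no missingness, all energies inside the fixed
#' plausibility window) and then plants exactly the requested violations on
#' disjoint records: implausible total energy (alternately below 2568 and
#' above 17031 kJ/d), missing baseline demographics (education set missing),
#' and missing physical activity. Every other record satisfies all three
#' criteria, so the exclusion cascade's behaviour on the fixture is known by
#' construction.
#'
#' @param n_total Total number of records.
#' @param n_energy_implausible Records with out-of-window energy.
#' @param n_missing_demog Records with a missing demographic field.
#' @param n_missing_pa Records with missing physical activity.
#' @param seed Integer seed.
#' @return A cohort tibble of `n_total` rows.
#' @export
#' @examples
#' fx <- make_exclusion_fixture(157, 6, 1, 3, seed = 11)
make_exclusion_fixture <- function(n_total, n_energy_implausible = 0,
                                   n_missing_demog = 0, n_missing_pa = 0,
                                   seed = 1L) {
  n_flag <- n_energy_implausible + n_missing_demog + n_missing_pa
  if (n_flag > n_total) {
    abort("make_exclusion_fixture(): flag counts exceed n_total")
  }
  cfg <- cohort_config(n_participants = n_total, seed = seed,
                       missingness = c(none = 0), item_missingness = 0)
  cohort <- generate_cohort(cfg)
  bounds <- fixed_energy_bounds()
  # clamp energies safely inside the window before planting violations
  cohort$total_energy <- pmin(pmax(cohort$total_energy, bounds[["lower"]] + 50),
                              bounds[["upper"]] - 50)
  withr::with_seed(seed + 1L, {
    idx <- sample.int(n_total, n_flag)
  })
  take <- function(k) {
    out <- head(idx, k)
    idx <<- idx[-seq_len(min(k, length(idx)))]
    out
  }
  i_energy <- take(n_energy_implausible)
  i_demog <- take(n_missing_demog)
  i_pa <- take(n_missing_pa)
  if (length(i_energy) > 0) {
    low <- i_energy[seq_along(i_energy) %% 2 == 1]
    high <- setdiff(i_energy, low)
    cohort$total_energy[low] <- bounds[["lower"]] * 0.5
    cohort$total_energy[high] <- bounds[["upper"]] * 1.2
  }
  cohort$education[i_demog] <- NA
  cohort$physical_activity[i_pa] <- NA
  cohort
}
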