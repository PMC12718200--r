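#' Configuration for the exposure-outcome model grid
#'
#' Enumerates 3 index exposures x 17 outcomes. BMI as an outcome is
#' structurally skipped for the WCRF/AICR and EHLI exposures (BMI is a
#' component of those scores), leaving 47 fitted models; the
#' multiple-comparison family nevertheless defaults to the full 3 x 17 = 51.
#' Per-index covariate sets: the MDS models adjust for age, total energy
#' (kcal/d), education, marital status, smoking, comorbidities, physical
#' activity and BMI; WCRF/AICR models omit BMI and physical activity; EHLI
#' models additionally omit smoking (all incorporated in those scores).
#' The four glycemic outcomes are modeled on the log scale.
#'
#' @param alpha Family-wise significance level.
#' @param family Size of the comparison family for the Bonferroni
#'   threshold.
#' @param subgroup Optional one-sided formula filtering the analytic
#'   samples before fitting (e.g. `~ age < 50`).
#' @param log_outcomes Outcomes modeled on the log scale.
#' @param conf_level Confidence level for the per-model CIs.
#' @return A list of class `grid_config`.
#' @export
grid_config <- function(alpha = 0.05, family = 51, subgroup = NULL,
                        log_outcomes = log_outcome_names(),
                        conf_level = 0.95) {
  base <- c("age", "energy_kcal", "education", "marital_status", "smoking",
            "comorbidities", "physical_activity", "bmi")
  structure(list(
    alpha = alpha, family = family, subgroup = subgroup,
    log_outcomes = log_outcomes, conf_level = conf_level,
    exposures = c(MDS = "mds_total", WCRF = "wcrf_total", EHLI = "ehli_total"),
    outcomes = outcome_names(),
    covariates = list(
      MDS = base,
      WCRF = setdiff(base, c("bmi", "physical_activity")),
      EHLI = setdiff(base, c("bmi", "physical_activity", "smoking"))
    ),
    skip = list(c("WCRF", "bmi"), c("EHLI", "bmi"))
  ), class = "grid_config")
}

# Add derived covariate columns expected by the grid.
prepare_analysis_data <- function(data) {
  if (!"energy_kcal" %in% names(data) && "total_energy" %in% names(data)) {
    data$energy_kcal <- kj_to_kcal(data$total_energy)
  }
  data
}

#' Fit the full exposure-outcome model grid
#'
#' Runs [fit_association()] over every (index, outcome) cell of the grid
#' defined by [grid_config()]: 47 fitted models plus 2 structurally skipped
#' BMI cells. The MDS models use the diet-only analytic sample; WCRF/AICR
#' and EHLI models use the diet-and-lifestyle sample. Each model is
#' complete-case, so per-row n varies. Cells whose fit fails are logged and
#' the grid continues. Evidence tiers are assigned with
#' [apply_bonferroni()] at the configured family size.
#'
#' @param diet_only Scored diet-only analytic sample (index totals,
#'   outcomes and covariates as columns).
#' @param diet_lifestyle Scored diet-and-lifestyle analytic sample; defaults
#'   to `diet_only`.
#' @param config A [grid_config()].
#' @return An object of class `dl_grid`: list with `results` (one row per
#'   fitted or failed cell), `skipped`, `threshold`, `family`, `alpha`.
#' @export
run_model_grid <- function(diet_only, diet_lifestyle = diet_only,
                           config = grid_config()) {
  diet_only <- prepare_analysis_data(diet_only)
  diet_lifestyle <- prepare_analysis_data(diet_lifestyle)
  if (!is.null(config$subgroup)) {
    keep <- function(d) {
      cond <- rlang::eval_tidy(rlang::f_rhs(config$subgroup), data = d)
      d[!is.na(cond) & cond, , drop = FALSE]
    }
    diet_only <- keep(diet_only)
    diet_lifestyle <- keep(diet_lifestyle)
  }
  cells <- tidyr::expand_grid(index = names(config$exposures),
                              outcome = config$outcomes)
  skip_key <- vapply(config$skip, paste, character(1), collapse = "|")
  cells$skipped <- paste(cells$index, cells$outcome, sep = "|") %in% skip_key

  fit_cell <- function(index, outcome) {
    dat <- if (index == "MDS") diet_only else diet_lifestyle
    covs <- config$covariates[[index]]
    covs <- setdiff(covs, outcome)  # never adjust an outcome for itself
    res <- tryCatch(
      fit_association(dat, config$exposures[[index]], outcome,
                      covariates = covs,
                      log_outcome = outcome %in% config$log_outcomes,
                      conf_level = config$conf_level),
      error = function(e) tibble::tibble(
        exposure = config$exposures[[index]], outcome = outcome,
        n_used = NA_integer_, estimate = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, p_value = NA_real_, scale = NA_character_,
        status = "failed", message = conditionMessage(e)))
    if (!"status" %in% names(res)) {
      res$status <- "ok"
      res$message <- NA_character_
    }
    res$index <- index
    res
  }
  fitted <- cells[!cells$skipped, ]
  results <- purrr::pmap_dfr(fitted[c("index", "outcome")], fit_cell)
  results <- apply_bonferroni(
    dplyr::relocate(results, "index"), config$family, config$alpha)
  structure(list(
    results = results,
    skipped = tibble::tibble(index = cells$index[cells$skipped],
                             outcome = cells$outcome[cells$skipped],
                             reason = "outcome incorporated in the index"),
    threshold = config$alpha / config$family,
    family = config$family, alpha = config$alpha,
    config = config
  ), class = "dl_grid")
}

#' @export
print.dl_grid <- function(x, ...) {
  ok <- sum(x$results$status == "ok")
  cat(sprintf("Model grid: %d fitted cells (%d failed), %d structurally skipped\n",
              ok, sum(x$results$status != "ok"), nrow(x$skipped)))
  cat(sprintf("Bonferroni family %d at alpha %.3g -> threshold %.4g\n",
              x$family, x$alpha, x$threshold))
  tiers <- table(x$results$tier)
  cat(sprintf("tiers: %s\n",
              paste(sprintf("%s %d", names(tiers), tiers), collapse = ", ")))
  invisible(x)
}

#' @describeIn run_model_grid Per-model results as a tibble.
#' @param x A `dl_grid`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dl_grid <- function(x, ...) x$results

#' @describeIn run_model_grid One-row grid summary.
#' @exportS3Method generics::glance
glance.dl_grid <- function(x, ...) {
  tibble::tibble(
    n_fitted = sum(x$results$status == "ok"),
    n_failed = sum(x$results$status != "ok"),
    n_skipped = nrow(x$skipped),
    family = x$family, alpha = x$alpha, threshold = x$threshold,
    n_strong = sum(x$results$tier == "strong", na.rm = TRUE),
    n_nominal = sum(x$results$tier == "nominal", na.rm = TRUE)
  )
}
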