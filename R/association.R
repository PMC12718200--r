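#' z-standardize an exposure
#'
#' Centers and scales to mean 0, SD 1 using the sample-SD (n-1) convention,
#' so regression coefficients on the result are per-SD effects. Computed
#' over the non-missing values of the supplied vector, which should be the
#' model's analytic sample.
#'
#' @param x Numeric vector with positive SD.
#' @return Numeric vector of z-scores (missing in, missing out).
#' @export
#' @examples
#' standardize_exposure(c(2, 4, 6)) # -1, 0, 1
standardize_exposure <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    abort("standardize_exposure(): exposure has zero variance")
  }
  (x - mean(x, na.rm = TRUE)) / s
}

#' Default reference levels for categorical covariates
#'
#' Indicator coding uses these first-listed levels as references:
#' education "high school or less", marital status "partner", smoking
#' "never", comorbidities "0".
#'
#' @return Named character vector.
#' @export
default_reference_levels <- function() {
  c(education = "high school or less", marital_status = "partner",
    smoking = "never", comorbidities = "0")
}

# Convert character covariates to factors with the configured reference
# level first.
encode_covariates <- function(data, refs = default_reference_levels()) {
  for (nm in intersect(names(refs), names(data))) {
    v <- data[[nm]]
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      if (refs[[nm]] %in% levels(v)) v <- stats::relevel(v, ref = refs[[nm]])
      data[[nm]] <- v
    }
  }
  data
}

#' Fit one covariate-adjusted association model
#'
#' Ordinary least squares of an outcome on the z-standardized exposure plus
#' encoded covariates, on complete cases. The exposure is standardized
#' within the model's complete-case analytic sample, so the coefficient is
#' the change in the outcome per 1 SD of exposure. When `log_outcome` the
#' response is the natural log of the outcome and the estimate and its 95%
#' CI are exponentiated back to the original scale. CIs come from the t
#' distribution with residual degrees of freedom.
#'
#' @param data Analysis tibble containing the exposure, outcome and
#'   covariate columns.
#' @param exposure,outcome Column names.
#' @param covariates Character vector of covariate column names.
#' @param log_outcome Model the log of the outcome and exponentiate the
#'   estimate.
#' @param conf_level Confidence level.
#' @param refs Reference levels for categorical covariates.
#' @return One-row tibble: `exposure`, `outcome`, `n_used`, `estimate`,
#'   `ci_low`, `ci_high`, `p_value`, `scale`.
#' @export
fit_association <- function(data, exposure, outcome, covariates = character(),
                            log_outcome = FALSE, conf_level = 0.95,
                            refs = default_reference_levels()) {
  check_columns(data, c(exposure, outcome, covariates), "fit_association")
  cols <- unique(c(exposure, outcome, covariates))
  d <- data[cols]
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n < length(covariates) + 2) {
    abort(sprintf("fit_association(): only %d complete cases for %s ~ %s; need at least %d",
                  n, outcome, exposure, length(covariates) + 2))
  }
  d <- encode_covariates(d, refs)
  y <- d[[outcome]]
  if (log_outcome) {
    if (any(y <= 0)) {
      abort(sprintf("fit_association(): outcome '%s' has nonpositive values; cannot log-transform",
                    outcome))
    }
    y <- log(y)
  }
  frame <- dplyr::bind_cols(tibble::tibble(.y = y,
                                           .z = standardize_exposure(d[[exposure]])),
                            d[covariates])
  fml <- as.formula(paste(".y ~ .z", paste(c("", covariates), collapse = " + ")))
  fit <- lm(fml, data = frame)
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort(sprintf("fit_association(): rank-deficient design for %s ~ %s; collinear column(s): %s",
                  outcome, exposure, paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  est <- cf[[".z"]]
  ci <- suppressWarnings(confint(fit, ".z", level = conf_level))
  # suppressed warning: summary.lm flags numerically perfect fits, which are
  # legitimate here (noiseless planted effects)
  p <- suppressWarnings(summary(fit))$coefficients[".z", "Pr(>|t|)"]
  if (log_outcome) {
    est <- exp(est)
    ci <- exp(ci)
  }
  tibble::tibble(exposure = exposure, outcome = outcome, n_used = n,
                 estimate = est, ci_low = ci[1], ci_high = ci[2],
                 p_value = p,
                 scale = if (log_outcome) "exponentiated" else "identity")
}

#' Assign Bonferroni evidence tiers
#'
#' Adds an evidence tier to a results table: `strong` when
#' `p < alpha / n_comparisons`, `nominal` when the p-value is below `alpha`
#' but not below the corrected threshold, `null` otherwise. With the
#' default family of 51 comparisons (3 indices x 17 outcomes) at
#' `alpha = 0.05` the corrected threshold is 0.05/51, approximately 0.001.
#'
#' @param results Tibble with a `p_value` column.
#' @param n_comparisons Size of the comparison family (>= 1).
#' @param alpha Family-wise significance level in (0, 1).
#' @return `results` with a `tier` factor column; the threshold is attached
#'   as the `"threshold"` attribute.
#' @export
apply_bonferroni <- function(results, n_comparisons = 51, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort("apply_bonferroni(): alpha must lie in (0, 1)")
  if (n_comparisons < 1) abort("apply_bonferroni(): n_comparisons must be >= 1")
  threshold <- alpha / n_comparisons
  results$tier <- factor(
    dplyr::case_when(is.na(results$p_value) ~ NA_character_,
                     results$p_value < threshold ~ "strong",
                     results$p_value < alpha ~ "nominal",
                     TRUE ~ "null"),
    levels = c("strong", "nominal", "null"))
  attr(results, "threshold") <- threshold
  results
}

#' Compare a characteristic across tertile groups
#'
#' Chi-square test (without continuity correction) for categorical
#' variables; for continuous variables, one-way ANOVA when the variable is
#' treated as approximately normal and Kruskal-Wallis otherwise. The
#' normality gate is configuration: variables named in `nonnormal` (by
#' default the four log-modeled glycemic outcomes) go to Kruskal-Wallis
#' rather than re-running a per-dataset test, but the Shapiro-Wilk p-value
#' of the ANOVA residuals is still computed and reported for continuous
#' variables. Low expected cell counts in the chi-square test are reported
#' as a warning.
#'
#' @param data Tibble holding the characteristic.
#' @param variable Column name of the characteristic.
#' @param tertiles Vector of group labels (e.g. from [assign_tertiles()]).
#' @param nonnormal Character vector of variables compared with
#'   Kruskal-Wallis.
#' @return One-row tibble: `variable`, `method`, `statistic`, `df`,
#'   `p_value`, `shapiro_p`.
#' @export
compare_by_tertile <- function(data, variable, tertiles,
                               nonnormal = log_outcome_names()) {
  check_columns(data, variable, "compare_by_tertile")
  x <- data[[variable]]
  g <- factor(tertiles)
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]
  g <- droplevels(g[keep])
  if (nlevels(g) < 2) {
    abort("compare_by_tertile(): need at least 2 non-empty tertile groups")
  }
  shapiro_p <- NA_real_
  if (is.numeric(x)) {
    if (variable %in% nonnormal) {
      ht <- kruskal.test(x, g)
      method <- "kruskal-wallis"
      df <- unname(ht$parameter)
    } else {
      fit <- aov(x ~ g)
      tab <- summary(fit)[[1]]
      ht <- list(statistic = tab[1, "F value"], p.value = tab[1, "Pr(>F)"])
      method <- "anova"
      df <- tab[1, "Df"]
    }
    res <- residuals(aov(x ~ g))
    if (length(res) >= 3 && length(res) <= 5000 && sd(res) > 0) {
      shapiro_p <- shapiro.test(res)$p.value
    }
  } else {
    tab <- table(x, g)
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    if (any(ht$expected < 5)) {
      warn(sprintf("compare_by_tertile(): expected cell counts below 5 for '%s'",
                   variable))
    }
    method <- "chi-square"
    df <- unname(ht$parameter)
  }
  tibble::tibble(variable = variable, method = method,
                 statistic = unname(ht$statistic), df = df,
                 p_value = ht$p.value, shapiro_p = shapiro_p)
}
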