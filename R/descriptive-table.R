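descriptive_defaults <- function() {
  list(
    categorical = c("race", "education", "income", "marital_status",
                    "menopausal_status", "smoking", "family_history",
                    "diabetes", "comorbidities"),
    mean_sd = c("bmi", "waist_cm", "hip_cm", "waist_hip_ratio",
                "facit_physical", "facit_social", "facit_emotional",
                "facit_functional", "facit_additional", "facit_general",
                "hads_anxiety", "hads_depression", "hads_overall"),
    median_iqr = c("hba1c", "fasting_insulin", "fasting_glucose", "homa_ir")
  )
}

fmt1 <- function(x) formatC(round(x, 1), format = "f", digits = 1)

cat_rows <- function(data, var) {
  v <- data[[var]]
  obs <- v[!is.na(v)]
  lev <- if (is.factor(obs)) levels(droplevels(obs)) else sort(unique(obs))
  rows <- purrr::map_dfr(lev, function(l) {
    n <- sum(obs == l)
    tibble::tibble(variable = var, level = as.character(l), n = n,
                   summary = format_count_pct(n, length(obs)))
  })
  if (any(is.na(v))) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      variable = var, level = "Missing", n = sum(is.na(v)),
      summary = as.character(sum(is.na(v)))))
  }
  rows
}

cont_row <- function(data, var, type) {
  v <- data[[var]]
  obs <- v[!is.na(v)]
  s <- if (length(obs) == 0) {
    "-"
  } else if (type == "mean_sd") {
    sprintf("%s (%s)", fmt1(mean(obs)), fmt1(sd(obs)))
  } else {
    sprintf("%s (%s)", fmt1(median(obs)), fmt1(stats::IQR(obs)))
  }
  tibble::tibble(variable = var,
                 level = if (type == "mean_sd") "mean (SD)" else "median (IQR)",
                 n = length(obs), summary = s)
}

#' Build a baseline descriptive table
#'
#' Renders a one-row-per-entry descriptive table in the style of a trial
#' baseline table: counts with one-decimal percentages for categorical
#' variables (percentages over non-missing, with a missing-count row),
#' mean (SD) or median (IQR) for continuous variables, per-component
#' adherence rows for each supplied index score table, and a good-quality
#' row (tertile 3) per index. Full precision is kept in the `n`/`pct`
#' columns; the `summary` column carries the rendered display string.
#'
#' @param data Cohort or analytic-sample tibble.
#' @param scores Optional named list of index score tables (as returned by
#'   [compute_mds()] etc.). If a table carries a `<prefix>_tertile` column
#'   it is used as-is; otherwise tertiles are assigned from the totals.
#' @param outcomes Optional outcome panel from [score_outcomes()] to
#'   summarize.
#' @param variables Variable configuration; see the defaults.
#' @return Tibble with `section`, `variable`, `level`, `n`, `summary`.
#' @export
build_descriptive_table <- function(data, scores = NULL, outcomes = NULL,
                                    variables = descriptive_defaults()) {
  sections <- list()
  present <- function(v) intersect(v, names(data))
  sections$characteristics <- purrr::map_dfr(present(variables$categorical),
                                             ~ cat_rows(data, .x))
  if (!is.null(outcomes)) {
    sections$outcomes <- dplyr::bind_rows(
      purrr::map_dfr(intersect(variables$median_iqr, names(outcomes)),
                     ~ cont_row(outcomes, .x, "median_iqr")),
      purrr::map_dfr(intersect(variables$mean_sd, names(outcomes)),
                     ~ cont_row(outcomes, .x, "mean_sd")))
  }
  if (!is.null(scores)) {
    sections$adherence <- purrr::imap_dfr(scores, function(tab, idx) {
      prefix <- tolower(idx)
      comp <- dplyr::select(tab, dplyr::starts_with(paste0(prefix, "_")),
                            -dplyr::matches("_(total|tertile|unscoreable)$"))
      max_scores <- vapply(comp, max, numeric(1), na.rm = TRUE)
      purrr::imap_dfr(comp, function(v, nm) {
        n_adh <- sum(!is.na(v) & v == max_scores[[nm]])
        tibble::tibble(variable = nm, level = "adherent", n = n_adh,
                       summary = format_count_pct(n_adh, sum(!is.na(v))))
      })
    })
    sections$good_quality <- purrr::imap_dfr(scores, function(tab, idx) {
      prefix <- tolower(idx)
      tert_col <- paste0(prefix, "_tertile")
      total_col <- paste0(prefix, "_total")
      tert <- if (tert_col %in% names(tab)) tab[[tert_col]] else
        assign_tertiles(tab[[total_col]])
      n_good <- sum(good_quality(tert), na.rm = TRUE)
      n_tot <- sum(!is.na(tert))
      tibble::tibble(variable = sprintf("Good diet/lifestyle quality (%s)", idx),
                     level = "tertile 3", n = n_good,
                     summary = format_count_pct(n_good, n_tot))
    })
  }
  dplyr::bind_rows(purrr::imap(sections, ~ dplyr::mutate(.x, section = .y,
                                                         .before = 1)))
}
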