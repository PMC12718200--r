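#' HADS severity category
#'
#' Maps a subscale total in `[0, 21]` to the standard categories: normal
#' (0-7), mild (8-10), moderate (11-14), severe (15-21). The four bands
#' partition the range with no gaps; prorated fractional totals fall into
#' the band whose upper bound they do not exceed (score < 8 is normal,
#' < 11 mild, < 15 moderate, otherwise severe).
#'
#' @param score Numeric subscale totals (possibly fractional after
#'   proration).
#' @return Ordered factor `normal < mild < moderate < severe`.
#' @export
#' @examples
#' hads_category(c(7, 8, 14, 15))
hads_category <- function(score) {
  lab <- dplyr::case_when(is.na(score) ~ NA_character_,
                          score < 8 ~ "normal",
                          score < 11 ~ "mild",
                          score < 15 ~ "moderate",
                          TRUE ~ "severe")
  factor(lab, levels = c("normal", "mild", "moderate", "severe"), ordered = TRUE)
}

#' Score the Hospital Anxiety and Depression Scale
#'
#' Fourteen items in 0-3: seven anxiety (`hads_a1..hads_a7`) and seven
#' depression (`hads_d1..hads_d7`) items, each subscale totalling 0-21.
#' Missing answers follow the same proration rules as the quality-of-life
#' score: a subscale is prorated when more than 50% of its items are
#' answered, and the overall score (anxiety + depression) is computed only
#' when more than 80% of all fourteen items are answered. Severity
#' categories are assigned from the subscale totals.
#'
#' @param data Tibble with the 14 HADS item columns (values in
#'   `{0..3, NA}`).
#' @return Tibble with `id`, `hads_anxiety`, `hads_depression`,
#'   `hads_overall`, `hads_anxiety_category`, `hads_depression_category`.
#' @export
score_hads <- function(data) {
  anx_cols <- paste0("hads_a", 1:7)
  dep_cols <- paste0("hads_d", 1:7)
  check_columns(data, c(anx_cols, dep_cols), "score_hads")
  mat <- as.matrix(data[c(anx_cols, dep_cols)])
  check_item_range(mat, 0, 3, "HADS")

  anxiety <- prorate_subscale(mat[, anx_cols, drop = FALSE])
  depression <- prorate_subscale(mat[, dep_cols, drop = FALSE])
  overall <- anxiety + depression
  overall[rowSums(!is.na(mat)) <= 0.8 * ncol(mat)] <- NA_real_

  tibble::tibble(
    id = record_ids(data),
    hads_anxiety = anxiety,
    hads_depression = depression,
    hads_overall = overall,
    hads_anxiety_category = hads_category(anxiety),
    hads_depression_category = hads_category(depression)
  )
}
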