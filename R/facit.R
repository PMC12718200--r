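#' Default FACIT scoring key
#'
#' Maps the 43 item columns to their five domains (physical, social,
#' emotional, functional and the disease-specific additional-concerns
#' domain; 7/7/6/7/16 items) and lists the reverse-scored items. Item
#' wording is instrument property, so the key only carries column names;
#' the reverse set here is a synthetic default matching the package's
#' cohort generator (all physical items, emotional items except the second,
#' and the first eight additional-concerns items are negatively worded).
#' Supply the instrument version's own key for real data.
#'
#' @return List with `domains` (named list of column names) and `reverse`
#'   (character vector).
#' @export
default_facit_key <- function() {
  list(
    domains = list(
      physical = paste0("facit_pw", 1:7),
      social = paste0("facit_sw", 1:7),
      emotional = paste0("facit_ew", 1:6),
      functional = paste0("facit_fw", 1:7),
      additional = paste0("facit_ec", 1:16)
    ),
    reverse = c(paste0("facit_pw", 1:7), paste0("facit_ew", c(1, 3:6)),
                paste0("facit_ec", 1:8))
  )
}

validate_facit_key <- function(key) {
  sizes <- vapply(key$domains, length, integer(1))
  expected <- facit_domain_sizes()
  if (!setequal(names(sizes), names(expected)) ||
      !all(sizes[names(expected)] == expected)) {
    abort("FACIT key must map 7/7/6/7/16 items to the physical/social/emotional/functional/additional domains")
  }
  items <- unlist(key$domains, use.names = FALSE)
  if (anyDuplicated(items) > 0) abort("FACIT key assigns an item to two domains")
  if (!all(key$reverse %in% items)) {
    abort("FACIT key reverse-scored items must be among the 43 domain items")
  }
  invisible(key)
}

# Prorated subscale score: reverse-map, then (sum of answered) * n/answered
# when more than half the items are answered, else missing.
prorate_subscale <- function(mat, min_fraction = 0.5) {
  n_items <- ncol(mat)
  answered <- rowSums(!is.na(mat))
  raw <- rowSums(mat, na.rm = TRUE)
  ifelse(answered / n_items > min_fraction, raw * n_items / answered, NA_real_)
}

#' Score the FACIT quality-of-life instrument
#'
#' 43 items in 0-4 across five domains. Reverse-scored items are mapped
#' `4 - x`. A subscale is prorated to its full-item scale when more than
#' 50% of its items are answered, otherwise missing; the general score is
#' the sum of the five subscales, computed only when more than 80% of all
#' 43 items are answered (and every subscale is computable). Prorated
#' scores are kept at full precision. The general score ranges 0-172.
#'
#' @param data Tibble with the 43 FACIT item columns (values in
#'   `{0..4, NA}`).
#' @param key Scoring key; see [default_facit_key()].
#' @return Tibble with `id`, `facit_physical`, `facit_social`,
#'   `facit_emotional`, `facit_functional`, `facit_additional`,
#'   `facit_general`.
#' @export
score_facit <- function(data, key = default_facit_key()) {
  validate_facit_key(key)
  items <- unlist(key$domains, use.names = FALSE)
  check_columns(data, items, "score_facit")
  mat <- as.matrix(data[items])
  check_item_range(mat, 0, 4, "FACIT")
  rev_cols <- intersect(items, key$reverse)
  mat[, rev_cols] <- 4 - mat[, rev_cols]

  out <- tibble::tibble(id = record_ids(data))
  for (dom in names(key$domains)) {
    out[[paste0("facit_", dom)]] <-
      prorate_subscale(mat[, key$domains[[dom]], drop = FALSE])
  }
  answered_all <- rowSums(!is.na(mat))
  subscales <- as.matrix(out[paste0("facit_", names(key$domains))])
  general <- rowSums(subscales)
  general[answered_all <= 0.8 * length(items)] <- NA_real_
  out$facit_general <- general
  out
}
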