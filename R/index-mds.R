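mds_intake_cols <- c("fruit_nuts", "vegetables", "cereals", "legumes",
                     "fish_seafood", "dairy", "red_meat", "processed_meat",
                     "mufa", "sfa", "alcohol")

#' Compute the Mediterranean diet score
#'
#' Nine binary components scored against cohort-internal medians, so the
#' data frame should be the diet-only analytic sample. Beneficial components
#' (fruit and nuts, vegetables, cereals, legumes, fish and seafood, and the
#' MUFA:SFA ratio) score 1 at or above the cohort median; dairy and meat
#' (red plus processed combined) score 1 strictly below the median; ethanol
#' scores 1 inside the moderate window (default 5 to <25 g/d). Totals range
#' 0-9.
#'
#' A zero SFA intake with positive MUFA gives an infinite ratio (scores 1
#' whenever the cohort median is finite); this is reported via a message.
#' A 0/0 ratio is treated as 0.
#'
#' @param data Diet-only analytic sample with g/d intake columns
#'   `fruit_nuts`, `vegetables`, `cereals`, `legumes`, `fish_seafood`,
#'   `dairy`, `red_meat`, `processed_meat`, `mufa`, `sfa`, `alcohol`.
#' @param cutpoints A [default_cutpoints()] list (only the ethanol window is
#'   used).
#' @return Tibble of per-record component scores (`mds_*`), `mds_total`, and
#'   the cohort medians as the `"medians"` attribute.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 20, seed = 1))
#' compute_mds(cohort)
compute_mds <- function(data, cutpoints = default_cutpoints()) {
  check_columns(data, mds_intake_cols, "compute_mds")
  validate_cutpoints(cutpoints)
  win <- cutpoints$mds

  ratio <- data$mufa / data$sfa
  inf_ratio <- !is.na(data$sfa) & data$sfa == 0 & !is.na(data$mufa) & data$mufa > 0
  if (any(inf_ratio)) {
    ratio[inf_ratio] <- Inf
    inform(sprintf("compute_mds(): SFA = 0 with MUFA > 0 for %d record(s); MUFA:SFA ratio treated as +Inf",
                   sum(inf_ratio)))
  }
  ratio[!is.na(data$sfa) & data$sfa == 0 & !is.na(data$mufa) & data$mufa == 0] <- 0

  meat <- data$red_meat + data$processed_meat
  beneficial <- list(fruit_nuts = data$fruit_nuts, vegetables = data$vegetables,
                     cereals = data$cereals, legumes = data$legumes,
                     fish_seafood = data$fish_seafood, mufa_sfa = ratio)
  detrimental <- list(dairy = data$dairy, meat = meat)

  scores <- tibble::tibble(.rows = nrow(data))
  medians <- c()
  for (nm in names(beneficial)) {
    med <- median(beneficial[[nm]], na.rm = TRUE)
    medians[nm] <- med
    scores[[paste0("mds_", nm)]] <- as.integer(beneficial[[nm]] >= med)
  }
  for (nm in names(detrimental)) {
    med <- median(detrimental[[nm]], na.rm = TRUE)
    medians[nm] <- med
    scores[[paste0("mds_", nm)]] <- as.integer(detrimental[[nm]] < med)
  }
  scores$mds_alcohol <- as.integer(!is.na(data$alcohol) &
                                     data$alcohol >= win$alcohol_lower &
                                     data$alcohol < win$alcohol_upper)
  scores$mds_total <- rowSums(dplyr::select(scores, dplyr::starts_with("mds_")))
  out <- dplyr::bind_cols(tibble::tibble(id = record_ids(data)), scores)
  attr(out, "medians") <- medians
  out
}
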