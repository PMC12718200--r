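#' Forest plot of a fitted model grid
#'
#' One panel per index, outcomes on the y axis, per-SD estimates with 95%
#' CIs on the x axis. Identity-scale and exponentiated (log-modeled)
#' outcomes are shown in separate facet rows so their null lines (0 and 1)
#' stay meaningful.
#'
#' @param object A `dl_grid` from [run_model_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dl_grid <- function(object, ...) {
  res <- dplyr::filter(object$results, .data$status == "ok")
  res$null <- ifelse(res$scale == "exponentiated", 1, 0)
  ggplot2::ggplot(res, ggplot2::aes(x = .data$estimate, y = .data$outcome,
                                    colour = .data$tier)) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$null),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.25) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(scale ~ index, scales = "free") +
    ggplot2::labs(x = "estimate per 1 SD of index score (95% CI)",
                  y = NULL, colour = "evidence") +
    ggplot2::theme_minimal()
}

#' Histogram of index score totals
#'
#' @param scores Named list of index score tables (as in
#'   [run_pipeline()]'s `scores` element) or a single score table.
#' @param binwidth Histogram bin width in score points.
#' @return A ggplot object.
#' @export
plot_score_distributions <- function(scores, binwidth = 0.5) {
  if (is.data.frame(scores)) scores <- list(index = scores)
  long <- purrr::imap_dfr(scores, function(tab, idx) {
    total_col <- grep("_total$", names(tab), value = TRUE)[1]
    tibble::tibble(index = idx, total = tab[[total_col]])
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$total)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "white") +
    ggplot2::facet_wrap(~index, scales = "free_x") +
    ggplot2::labs(x = "index total", y = "participants") +
    ggplot2::theme_minimal()
}
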