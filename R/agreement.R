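#' Spearman rank correlation between two index scores
#'
#' Rank correlation with average ranks for ties; the p-value comes from the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees
#' of freedom (p = 0 at |rho| = 1).
#'
#' @param x,y Paired numeric vectors (pairs with any missing value are
#'   dropped; at least 3 complete pairs required).
#' @return One-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman_between <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) abort("spearman_between(): need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("spearman_between(): rank correlation undefined for a constant vector")
  }
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), n - 2)
  }
  tibble::tibble(rho = rho, p_value = p, n = n)
}

#' Weighted kappa between two ordinal classifications
#'
#' Chance-corrected agreement `kappa = 1 - sum(w * p_obs) / sum(w * p_exp)`
#' with disagreement weights `w_ij = |i - j| / (k - 1)` (linear,
#' Cicchetti-Allison, the default) or its square (quadratic,
#' Fleiss-Cohen); expected proportions come from the marginal products.
#' The p-value tests kappa = 0 with the large-sample null variance of
#' Fleiss, Cohen and Everitt.
#'
#' @param x,y Paired ordinal labels on the same scale (factors or values
#'   coercible to a common level set).
#' @param weights `"linear"` or `"quadratic"`.
#' @param levels Optional common level set; defaults to the sorted union of
#'   observed levels.
#' @return One-row tibble: `kappa`, `p_value`, `n`, `weights`.
#' @export
#' @examples
#' weighted_kappa(c(1, 2, 3, 3), c(1, 2, 3, 2))
weighted_kappa <- function(x, y, weights = c("linear", "quadratic"),
                           levels = NULL) {
  weights <- match.arg(weights)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  levels <- levels %||% sort(unique(c(as.character(x), as.character(y))))
  k <- length(levels)
  fx <- factor(as.character(x), levels = levels)
  fy <- factor(as.character(y), levels = levels)
  if (length(unique(fx)) < 2 || length(unique(fy)) < 2) {
    abort("weighted_kappa(): degenerate marginals (a rater uses a single category)")
  }
  if (k < 2) abort("weighted_kappa(): need at least 2 categories")
  n <- length(fx)
  p <- table(fx, fy) / n
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  if (weights == "quadratic") d <- d^2
  po_d <- sum(d * p)
  pe_d <- sum(d * outer(pi_, pj_))
  if (pe_d == 0) abort("weighted_kappa(): expected disagreement is zero")
  kappa <- 1 - po_d / pe_d

  # Fleiss-Cohen-Everitt null variance, agreement-weight form
  w <- 1 - d
  pe_w <- sum(w * outer(pi_, pj_))
  wbar_i <- as.vector(w %*% pj_)      # row-wise expected agreement weight
  wbar_j <- as.vector(t(w) %*% pi_)   # column-wise
  var0 <- (sum(outer(pi_, pj_) * (w - outer(wbar_i, wbar_j, "+"))^2) - pe_w^2) /
    (n * (1 - pe_w)^2)
  p_value <- if (var0 <= 0) NA_real_ else 2 * pnorm(-abs(kappa / sqrt(var0)))
  tibble::tibble(kappa = kappa, p_value = p_value, n = n, weights = weights)
}

#' Pairwise agreement between index scores
#'
#' For every pair of indices computes the Spearman correlation of the
#' continuous totals and the weighted kappa of the tertile
#' classifications (tertiles assigned per index with [assign_tertiles()]
#' over the supplied sample).
#'
#' @param data Tibble holding the index total columns.
#' @param score_cols Named character vector mapping index labels to total
#'   columns.
#' @param weights Kappa weighting scheme.
#' @return Tibble with one row per unordered pair: `index_a`, `index_b`,
#'   `spearman_rho`, `spearman_p`, `weighted_kappa`, `kappa_p`, `weights`,
#'   `n`.
#' @export
index_agreement <- function(data,
                            score_cols = c(MDS = "mds_total",
                                           WCRF = "wcrf_total",
                                           EHLI = "ehli_total"),
                            weights = "linear") {
  check_columns(data, unname(score_cols), "index_agreement")
  labels <- names(score_cols)
  tert <- lapply(score_cols, function(cl) assign_tertiles(data[[cl]]))
  pairs <- utils::combn(labels, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- pr[1]
    b <- pr[2]
    sp <- spearman_between(data[[score_cols[[a]]]], data[[score_cols[[b]]]])
    kp <- weighted_kappa(tert[[a]], tert[[b]], weights = weights,
                         levels = c("1", "2", "3"))
    tibble::tibble(index_a = a, index_b = b,
                   spearman_rho = sp$rho, spearman_p = sp$p_value,
                   weighted_kappa = kp$kappa, kappa_p = kp$p_value,
                   weights = kp$weights, n = sp$n)
  })
}
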