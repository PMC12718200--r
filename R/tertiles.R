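#' Assign tertiles of an index total
#'
#' Cuts a numeric vector at its empirical 1/3 and 2/3 quantiles (type-7).
#' Values tied with a boundary quantile are all assigned to the lower
#' tertile (assignment is `1 + (x > q1) + (x > q2)`, strict inequalities).
#' Tertile 3 marks good overall adherence. If all values are identical a
#' single tertile is returned with a warning.
#'
#' @param x Numeric vector of index totals (>= 3 non-missing values).
#' @param na.rm Keep records with missing totals as missing tertiles.
#' @return Integer vector of labels in `{1, 2, 3}` (NA where `x` is NA),
#'   with attributes `"cuts"` (the two quantiles) and `"sizes"` (group
#'   sizes).
#' @export
#' @examples
#' assign_tertiles(rep(1:9, each = 1))
assign_tertiles <- function(x, na.rm = TRUE) {
  obs <- x[!is.na(x)]
  if (length(obs) < 3) {
    abort("assign_tertiles(): need at least 3 non-missing values")
  }
  if (length(unique(obs)) == 1) {
    warn("assign_tertiles(): all values identical; a single tertile was assigned")
    out <- ifelse(is.na(x), NA_integer_, 1L)
    attr(out, "cuts") <- c(obs[1], obs[1])
    attr(out, "sizes") <- c(`1` = length(obs))
    return(out)
  }
  q <- quantile(obs, c(1, 2) / 3, type = 7, names = FALSE)
  out <- 1L + (x > q[1]) + (x > q[2])
  out <- as.integer(out)
  attr(out, "cuts") <- q
  attr(out, "sizes") <- table(out, dnn = NULL)
  out
}

#' Good-adherence flag from tertiles
#'
#' @param tertiles Output of [assign_tertiles()].
#' @return Logical vector, `TRUE` for tertile 3.
#' @export
good_quality <- function(tertiles) tertiles == 3L
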