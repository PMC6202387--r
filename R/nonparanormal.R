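#' Nonparanormal (rank-based gaussianization) transformation
#'
#' Maps a continuous column to approximate normality: average ranks are
#' turned into the empirical CDF \eqn{r/(n+1)}, truncated to
#' \eqn{[\delta_n, 1-\delta_n]} with
#' \eqn{\delta_n = 1/(4 n^{1/4} \sqrt{\pi \log n})}, passed through the
#' standard-normal quantile function, and rescaled to unit sample
#' variance. Strictly monotone in the input
#' ranks; ties map to equal outputs; `NA`s are preserved.
#'
#' @param x numeric vector with at least two distinct observed values.
#' @param n observation count used for the truncation constant; defaults
#'   to the number of non-missing values.
#' @return Transformed numeric vector of the same length.
#' @export
nonparanormal_transform <- function(x, n = sum(!is.na(x))) {
  obs <- !is.na(x)
  if (length(unique(x[obs])) < 2)
    stop("nonparanormal transform needs >= 2 distinct values")
  r <- rank(x[obs], ties.method = "average")
  u <- r / (n + 1)
  delta <- 1 / (4 * n^0.25 * sqrt(pi * log(n)))
  u <- pmin(pmax(u, delta), 1 - delta)
  q <- qnorm(u)
  out <- x
  out[obs] <- q / sd(q)
  out
}

#' Pooled transformation before group split
#'
#' Applies [nonparanormal_transform()] to every continuous column of a
#' two-group study table on the pooled sample, then leaves the rows (and
#' group labels) in place. Transforming before splitting guarantees both
#' groups share one scale, which the permutation comparison tests require
#' for exchangeability.
#'
#' @param table a two-group [study_table()].
#' @return The table with continuous columns transformed.
#' @export
pooled_transform_then_split <- function(table) {
  stopifnot(inherits(table, "rf_study_table"))
  if (nlevels(table$group) != 2)
    stop("pooled transformation expects exactly two groups")
  vals <- table$values
  for (j in which(table$var_types == "continuous"))
    vals[, j] <- nonparanormal_transform(vals[, j])
  study_table(vals, as.character(table$group), table$var_types,
              table$var_roles)
}
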