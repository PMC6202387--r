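# Descriptive two-group comparison statistics: Welch t, 2x2 chi-square
# with continuity correction, Cochran-Armitage trend test.

test_result <- function(statistic, df, p, ci, method) {
  if (!is.na(p) && (p < 0 || p > 1)) stop("invalid p-value")
  structure(list(statistic = unname(statistic), df = unname(df),
                 p = unname(p), ci = unname(ci), method = method),
            class = "rf_test")
}

#' @export
print.rf_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 4),
      if (!is.null(x$df) && !is.na(x$df[1]))
        paste0(" (df = ", format(x$df, digits = 5), ")"),
      ", p = ", format.pval(x$p, digits = 3), "\n", sep = "")
  if (!is.null(x$ci))
    cat("  95% CI: [", format(x$ci[1], digits = 3), ", ",
        format(x$ci[2], digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Satterthwaite degrees of freedom and a
#' 95% CI for the mean difference.
#'
#' @param x,y numeric samples (>= 2 non-missing each).
#' @return An `rf_test` result.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs >= 2 non-missing observations")
  if (var(x) == 0 && var(y) == 0) stop("zero variance in both groups")
  tt <- t.test(x, y, var.equal = FALSE)
  test_result(tt$statistic, tt$parameter, tt$p.value, as.vector(tt$conf.int),
              "Welch two-sample t-test")
}

#' 2x2 Pearson chi-square test
#'
#' With `continuity = TRUE` (the default) applies the Yates correction
#' `X^2 = N (|ad - bc| - N/2)^2 / (r1 r2 c1 c2)`.
#'
#' @param counts 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @param continuity apply the continuity correction.
#' @return An `rf_test` result (df = 1).
#' @export
#' @examples
#' chisq_2x2(matrix(c(494, 435, 119, 56), 2))  # 12.51
chisq_2x2 <- function(counts, continuity = TRUE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be 2x2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin")
  ct <- suppressWarnings(chisq.test(counts, correct = continuity))
  test_result(ct$statistic, 1, ct$p.value, NULL,
              paste0("Pearson chi-square",
                     if (continuity) " (continuity corrected)"))
}

#' Asymptotic Cochran-Armitage trend test
#'
#' Tests for a linear trend in the proportion of group membership across
#' ordered categories of a 2 x k table, using the definitional sums:
#' `T = sum s_k n_1k` with hypergeometric null moments
#' `E[T] = R1 sum(s c)/N` and
#' `Var[T] = R1 R2 (N sum(s^2 c) - (sum(s c))^2) / (N^2 (N - 1))`.
#' Two-tailed normal p-value.
#'
#' @param counts 2 x k matrix (k >= 3), rows = groups, columns = ordered
#'   categories.
#' @param scores strictly monotone category scores (default `1..k`).
#' @return An `rf_test` result with the trend z statistic.
#' @export
cochran_armitage <- function(counts, scores = seq_len(ncol(counts))) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2 || ncol(counts) < 3)
    stop("counts must be a 2 x k table with k >= 3")
  if (any(colSums(counts) == 0)) stop("zero column total")
  if (!(all(diff(scores) > 0) || all(diff(scores) < 0)))
    stop("scores must be strictly monotone")
  N <- sum(counts)
  R1 <- sum(counts[1, ]); R2 <- sum(counts[2, ])
  cc <- colSums(counts)
  T_obs <- sum(scores * counts[1, ])
  ET <- R1 * sum(scores * cc) / N
  VT <- R1 * R2 * (N * sum(scores^2 * cc) - sum(scores * cc)^2) /
    (N^2 * (N - 1))
  z <- (T_obs - ET) / sqrt(VT)
  test_result(z, NA, 2 * pnorm(-abs(z)), NULL,
              "Cochran-Armitage trend test (asymptotic)")
}

#' Batch descriptive comparison of a two-group study table
#'
#' Emits one row per non-item variable: group summaries, the matching
#' test (Welch t for continuous, continuity-corrected chi-square for
#' binary), p-value and CI where defined.
#'
#' @param table a two-group [study_table()].
#' @return A data.frame, one row per variable.
#' @export
table_one <- function(table) {
  stopifnot(inherits(table, "rf_study_table"))
  if (nlevels(table$group) != 2) stop("table_one needs two groups")
  g <- levels(table$group)
  vars <- names(table$var_roles)[table$var_roles != "item"]
  rows <- lapply(vars, function(v) {
    x <- table$values[table$group == g[1], v]
    y <- table$values[table$group == g[2], v]
    if (table$var_types[[v]] == "continuous") {
      tt <- welch_t(x, y)
      data.frame(variable = v, type = "continuous",
                 summary_a = sprintf("M = %.2f", mean(x, na.rm = TRUE)),
                 summary_b = sprintf("M = %.2f", mean(y, na.rm = TRUE)),
                 statistic = tt$statistic, df = tt$df, p = tt$p,
                 ci_lower = tt$ci[1], ci_upper = tt$ci[2])
    } else {
      cnt <- rbind(c(sum(x == 1, na.rm = TRUE), sum(x == 0, na.rm = TRUE)),
                   c(sum(y == 1, na.rm = TRUE), sum(y == 0, na.rm = TRUE)))
      ct <- chisq_2x2(cnt)
      data.frame(variable = v, type = table$var_types[[v]],
                 summary_a = sprintf("1: %d / 0: %d", cnt[1, 1], cnt[1, 2]),
                 summary_b = sprintf("1: %d / 0: %d", cnt[2, 1], cnt[2, 2]),
                 statistic = ct$statistic, df = 1, p = ct$p,
                 ci_lower = NA_real_, ci_upper = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
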