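#' Two-step polychoric correlation
#'
#' Estimates the latent-normal correlation of two ordinal (or binary)
#' variables. Step one fixes the thresholds at the inverse-normal marginal
#' cumulative proportions; step two maximizes the bivariate-normal
#' cell-probability log-likelihood over rho by bounded scalar search
#' (tolerance 1e-6). Bivariate rectangle probabilities use a
#' Gauss-Legendre quadrature with absolute error well below 1e-7.
#'
#' @param x,y ordinal vectors (any numeric coding; `NA` dropped pairwise).
#' @return The estimated correlation, in (-1, 1).
#' @export
estimate_polychoric <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10) stop("polychoric estimation needs pair n >= 10")
  tab <- table(factor(x), factor(y))
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("polychoric estimation needs >= 2 observed categories per column")
  tau_x <- qnorm(cumsum(rowSums(tab))[-nrow(tab)] / sum(tab))
  tau_y <- qnorm(cumsum(colSums(tab))[-ncol(tab)] / sum(tab))
  n <- tab
  ll <- function(rho) {
    P <- .bvn_cell_probs(tau_x, tau_y, rho)
    v <- sum(n * log(pmax(P, 1e-12)))
    if (!is.finite(v)) stop("non-finite polychoric likelihood")
    v
  }
  eps <- 1e-6
  optimize(ll, c(-1 + eps, 1 - eps), maximum = TRUE, tol = 1e-6)$maximum
}

#' Two-step polyserial correlation
#'
#' Latent-normal correlation between a continuous and an ordinal (or
#' binary) variable: the continuous margin is standardized, the ordinal
#' thresholds fixed from the marginal proportions, and rho maximizes the
#' conditional-normal log-likelihood by bounded scalar search.
#'
#' @param x continuous vector.
#' @param y ordinal vector.
#' @return The estimated correlation, in (-1, 1).
#' @export
estimate_polyserial <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10) stop("polyserial estimation needs pair n >= 10")
  if (sd(x) == 0) stop("continuous column constant after deletion")
  yf <- factor(y)
  if (nlevels(yf) < 2)
    stop("polyserial estimation needs >= 2 observed categories")
  z <- (x - mean(x)) / sd(x)
  prop <- cumsum(table(yf)) / length(y)
  tau <- c(-Inf, qnorm(prop[-nlevels(yf)]), Inf)
  k <- as.integer(yf)
  ll <- function(rho) {
    s <- sqrt(1 - rho^2)
    p <- pnorm((tau[k + 1] - rho * z) / s) - pnorm((tau[k] - rho * z) / s)
    v <- sum(log(pmax(p, 1e-12)))
    if (!is.finite(v)) stop("non-finite polyserial likelihood")
    v
  }
  eps <- 1e-6
  optimize(ll, c(-1 + eps, 1 - eps), maximum = TRUE, tol = 1e-6)$maximum
}

#' Auto-typed mixed correlation matrix
#'
#' Builds the full correlation matrix of a study table, choosing the
#' estimator per pair from the variable types: Pearson for two continuous
#' variables, polychoric for two ordinal/binary variables, polyserial for
#' a mixed pair. Under `"pairwise"` deletion each pair uses its complete
#' cases; `"listwise"` first restricts to rows complete on every column.
#' If the assembled matrix is not positive definite its eigenvalues are
#' clipped at 1e-6 and the matrix renormalized to unit diagonal
#' (`psd_adjusted` flags this).
#'
#' @param table an [study_table()] object (all of its columns are used).
#' @param deletion `"pairwise"` (default) or `"listwise"`.
#' @return An object of class `rf_mixed_cor`: `values` (correlation
#'   matrix), `method` (per-pair tag matrix), `pair_n`, `psd_adjusted`.
#' @export
auto_correlation_matrix <- function(table,
                                    deletion = c("pairwise", "listwise")) {
  stopifnot(inherits(table, "rf_study_table"))
  deletion <- match.arg(deletion)
  X <- table$values
  if (deletion == "listwise") X <- X[complete.cases(X), , drop = FALSE]
  p <- ncol(X)
  if (p < 2) stop("need >= 2 variables")
  cont <- table$var_types == "continuous"
  labs <- colnames(X)
  R <- diag(p)
  meth <- matrix("", p, p, dimnames = list(labs, labs))
  pair_n <- matrix(nrow(X), p, p, dimnames = list(labs, labs))
  dimnames(R) <- list(labs, labs)
  if (all(cont)) {                      # vectorized all-Pearson branch
    pair_n <- crossprod(!is.na(X))
    if (min(pair_n[upper.tri(pair_n)]) < 10) {
      bad <- which(pair_n < 10 & upper.tri(pair_n), arr.ind = TRUE)[1, ]
      stop("insufficient data (n = ", pair_n[bad[1], bad[2]],
           ") for pair ", labs[bad[1]], " - ", labs[bad[2]])
    }
    R <- cor(X, use = "pairwise.complete.obs")
    meth[] <- "pearson"
    diag(meth) <- ""
    return(psd_repair(R, meth, pair_n))
  }
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    ok <- !is.na(X[, i]) & !is.na(X[, j])
    nij <- sum(ok)
    pair_n[i, j] <- pair_n[j, i] <- nij
    if (nij < 10)
      stop("insufficient data (n = ", nij, ") for pair ",
           labs[i], " - ", labs[j])
    if (cont[i] && cont[j]) {
      r <- cor(X[ok, i], X[ok, j])
      m <- "pearson"
    } else if (!cont[i] && !cont[j]) {
      r <- estimate_polychoric(X[ok, i], X[ok, j])
      m <- "polychoric"
    } else {
      cc <- if (cont[i]) X[ok, i] else X[ok, j]
      oo <- if (cont[i]) X[ok, j] else X[ok, i]
      r <- estimate_polyserial(cc, oo)
      m <- "polyserial"
    }
    R[i, j] <- R[j, i] <- r
    meth[i, j] <- meth[j, i] <- m
  }
  psd_repair(R, meth, pair_n)
}

# eigenvalue clipping at 1e-6 + renormalization to unit diagonal
psd_repair <- function(R, meth, pair_n) {
  labs <- colnames(R)
  psd_adjusted <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    lam <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% (lam * t(ev$vectors))
    R <- stats::cov2cor(R)
    R <- (R + t(R)) / 2
    dimnames(R) <- list(labs, labs)
    psd_adjusted <- TRUE
  }
  structure(list(values = R, method = meth, pair_n = pair_n,
                 psd_adjusted = psd_adjusted),
            class = "rf_mixed_cor")
}

#' @export
print.rf_mixed_cor <- function(x, ...) {
  cat("Mixed correlation matrix (", ncol(x$values), " variables, ",
      "min pair n = ", min(x$pair_n[upper.tri(x$pair_n)]),
      if (x$psd_adjusted) ", PSD-adjusted" else "", ")\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}
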