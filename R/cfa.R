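#' One-factor CFA by unweighted least squares
#'
#' Fits a single-factor model to an item correlation matrix (typically
#' polychoric) by minimizing the off-diagonal discrepancy
#' `sum_{i<j} (s_ij - l_i l_j)^2`. Deterministic multi-start rule: the
#' first-principal-component loadings, their negation, and a flat 0.5
#' vector are each polished by BFGS and the best solution kept; the sign
#' is normalized so the loading sum is non-negative.
#'
#' @param poly item correlation matrix, or an `rf_mixed_cor` object (its
#'   `values` are used).
#' @param thresholds optional list of per-item threshold vectors, carried
#'   into the returned model for scoring metadata.
#' @return An object of class `rf_factor_model` with `loadings`,
#'   `thresholds`, and `fit_residual` (the minimized discrepancy).
#' @export
#' @examples
#' R <- matrix(0.49, 3, 3); diag(R) <- 1
#' fit_one_factor_cfa(R)$loadings  # 0.7, 0.7, 0.7
fit_one_factor_cfa <- function(poly, thresholds = NULL) {
  S <- if (inherits(poly, "rf_mixed_cor")) poly$values else as.matrix(poly)
  m <- ncol(S)
  if (m < 3)
    stop("one-factor CFA needs >= 3 items; for 1-2 items use the ",
         "standardized item directly")
  up <- upper.tri(S)
  obj <- function(l) sum((S[up] - tcrossprod(l)[up])^2)
  if (max(abs(S[up])) < 1e-10) {
    lam <- rep(0, m)
  } else {
    e <- eigen(S, symmetric = TRUE)
    s0 <- e$vectors[, 1] * sqrt(max(e$values[1], 0))
    s0 <- pmin(pmax(s0, -0.95), 0.95)
    starts <- list(s0, -s0, rep(0.5, m))
    fits <- lapply(starts, function(s)
      optim(s, obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)))
    lam <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]$par
    if (sum(lam) < 0) lam <- -lam
  }
  names(lam) <- colnames(S)
  structure(list(loadings = lam, thresholds = thresholds,
                 fit_residual = obj(lam)),
            class = "rf_factor_model")
}

#' Regression-method (Thurstone) factor scores
#'
#' Scores persons on a fitted one-factor model from standardized numeric
#' item codes, using the model-implied item correlation matrix
#' `LL' + diag(1 - L^2)`. Persons with some missing items are scored from
#' the observed subset's sub-model; persons with all items missing get
#' `NA`. Scores are standardized to mean 0, variance 1 over the pooled
#' non-missing sample.
#'
#' @param model an [fit_one_factor_cfa()] result.
#' @param items numeric matrix of item codes (columns match the model's
#'   loadings).
#' @return Numeric score vector, one per row of `items`.
#' @export
factor_scores <- function(model, items) {
  stopifnot(inherits(model, "rf_factor_model"))
  items <- as.matrix(items)
  L <- model$loadings
  if (ncol(items) != length(L))
    stop("item block does not match the model's loadings")
  Z <- scale(items)
  Rm <- tcrossprod(L) + diag(1 - L^2, length(L))
  scores <- rep(NA_real_, nrow(items))
  pat <- apply(!is.na(Z), 1, paste, collapse = "")
  for (pt in unique(pat)) {
    idx <- which(pat == pt)
    ob <- !is.na(Z[idx[1], ])
    if (!any(ob)) next
    w <- solve(Rm[ob, ob, drop = FALSE], L[ob])
    scores[idx] <- Z[idx, ob, drop = FALSE] %*% w
  }
  ok <- !is.na(scores)
  scores[ok] <- (scores[ok] - mean(scores[ok])) / sd(scores[ok])
  scores
}

#' Dichotomize a range-restricted variable
#'
#' Collapses a score with a dominant mass point to a 0/1 indicator, coding
#' the protective (restricted) level 1 and everything else 0 — the coding
#' convention of scales where most respondents sit at the protective end.
#'
#' @param x numeric vector (missing preserved).
#' @param protective the value(s) mapped to 1; defaults to the most
#'   frequent observed value.
#' @return Binary 0/1 vector.
#' @export
dichotomize_restricted <- function(x, protective = NULL) {
  obs <- x[!is.na(x)]
  if (is.null(protective)) {
    tt <- table(obs)
    protective <- as.numeric(names(tt)[which.max(tt)])
  }
  if (!any(protective %in% obs))
    stop("protective value outside the observed range")
  out <- ifelse(is.na(x), NA_real_, as.numeric(x %in% protective))
  oo <- out[!is.na(out)]
  if (all(oo == 1) || all(oo == 0))
    stop("degenerate dichotomization: all values fall on one side")
  out
}
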