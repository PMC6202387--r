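#' Construct a network object
#'
#' @param weights symmetric matrix, zero diagonal, |entries| < 1.
#' @param labels node names (defaults to the matrix dimnames).
#' @param node_types per-node `"continuous"`/`"binary"` flags.
#' @param kind `"regularized_partial"` or `"zero_order"`.
#' @param meta list of estimator metadata (selected lambda, gamma, n, ...).
#' @return An object of class `rf_network`.
#' @export
new_network <- function(weights, labels = colnames(weights),
                        node_types = NULL,
                        kind = c("regularized_partial", "zero_order"),
                        meta = list()) {
  weights <- as.matrix(weights)
  kind <- match.arg(kind)
  p <- ncol(weights)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  if (is.null(node_types)) node_types <- rep("continuous", p)
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-8)))
    stop("network weights must be symmetric")
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) stop("network weights need a zero diagonal")
  if (any(abs(weights) >= 1)) stop("edge weights must satisfy |w| < 1")
  dimnames(weights) <- list(labels, labels)
  structure(list(labels = labels, weights = weights,
                 node_types = node_types, kind = kind, meta = meta),
            class = "rf_network")
}

#' @export
print.rf_network <- function(x, ...) {
  e <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("%s network: %d nodes, %d edges\n",
              ifelse(x$kind == "zero_order", "Association",
                     "Regularized partial correlation"),
              length(x$labels), e))
  if (!is.null(x$meta$lambda))
    cat(sprintf("  lambda = %.4g (gamma = %.2g, n = %d)\n",
                x$meta$lambda, x$meta$gamma, x$meta$n))
  invisible(x)
}

#' Graphical lasso fit at a single penalty
#'
#' Solves the L1-penalized Gaussian log-determinant problem
#' `max_K log det K - tr(SK) - lam * sum_{i != j} |K_ij|` (off-diagonal
#' penalty only) by block coordinate descent, converging when the maximum
#' absolute parameter change drops below `tol`.
#'
#' @param S symmetric positive-definite correlation matrix.
#' @param lam penalty, `>= 0`.
#' @param tol convergence tolerance (default 1e-6).
#' @param maxit outer iteration cap.
#' @return The estimated precision matrix (exact zeros where the penalty
#'   removes an edge).
#' @export
glasso_fit <- function(S, lam, tol = 1e-6, maxit = 500) {
  S <- as.matrix(S)
  if (lam < 0) stop("lam must be >= 0")
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
    stop("S must be symmetric")
  fit <- .glasso_single((S + t(S)) / 2, lam, tol, maxit)
  if (!fit$converged)
    stop("graphical lasso did not converge in ", maxit,
         " iterations (lam = ", format(lam), ", p = ", ncol(S), ")")
  K <- fit$K
  dimnames(K) <- dimnames(S)
  K
}

#' Precision matrix to partial correlations
#'
#' `w_ij = -K_ij / sqrt(K_ii K_jj)` with a zero diagonal.
#'
#' @param K symmetric precision matrix with positive diagonal.
#' @return Partial correlation matrix.
#' @export
precision_to_partials <- function(K) {
  K <- as.matrix(K)
  if (any(diag(K) <= 0)) stop("precision diagonal must be positive")
  d <- 1 / sqrt(diag(K))
  W <- -K * tcrossprod(d)
  diag(W) <- 0
  dimnames(W) <- dimnames(K)
  W
}

#' EBIC-selected graphical lasso network
#'
#' Fits a warm-started graphical lasso path over `n_lambda` log-spaced
#' penalties from `lambda_max = max |off-diagonal of S|` down to
#' `lambda_max * lambda_min_ratio`, scores each model with
#' `EBIC = -2 L + E log n + 4 E gamma log p` where `E` counts nonzero
#' upper-triangle entries and `L = (n/2)(log det K - tr(SK))` is evaluated
#' at the maximum-likelihood precision matrix restricted to the selected
#' support (the refit scoring of the original EBIC construction for
#' Gaussian graphical models, which keeps lasso shrinkage out of the
#' model comparison), and returns the EBIC-minimizing network whose edge
#' weights are the regularized partial correlations at the selected
#' penalty. EBIC ties are resolved toward the sparser support and, within
#' one support, toward the smallest penalty so the reported weights carry
#' minimal shrinkage.
#'
#' @param S correlation matrix or `rf_mixed_cor` (pairwise estimation uses
#'   the minimum pairwise n unless `n` is given).
#' @param n sample size for the likelihood term.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda,lambda_min_ratio path geometry (defaults 100, 0.01).
#' @param labels,node_types optional node metadata.
#' @return List with `network` (the selected [new_network()]) and `path`
#'   (class `rf_penalty_path`: per-lambda EBIC bookkeeping).
#' @export
ebic_glasso_network <- function(S, n, gamma = 0.5, n_lambda = 100,
                                lambda_min_ratio = 0.01,
                                labels = NULL, node_types = NULL) {
  if (inherits(S, "rf_mixed_cor")) {
    if (missing(n)) n <- min(S$pair_n[upper.tri(S$pair_n)])
    S <- S$values
  }
  S <- as.matrix(S)
  p <- ncol(S)
  if (is.null(labels)) labels <- colnames(S)
  if (n <= p)
    warning("sample size n = ", n, " does not exceed p = ", p,
            "; the selected network may be unstable")
  if (gamma < 0) stop("gamma must be >= 0")
  core <- ebic_path_core(S, n, gamma, n_lambda, lambda_min_ratio)
  if (is.null(core$path)) {              # exact independence input
    net <- new_network(matrix(0, p, p), labels, node_types,
                       "regularized_partial",
                       list(lambda = NA_real_, gamma = gamma, n = n))
    return(list(network = net, path = NULL))
  }
  K <- core$K
  dimnames(K) <- list(labels, labels)
  net <- new_network(precision_to_partials(K), labels, node_types,
                     "regularized_partial",
                     list(lambda = core$lambda, gamma = gamma, n = n,
                          precision = K))
  list(network = net, path = core$path)
}

# shared EBIC path core; returns the selected precision matrix and the
# per-lambda bookkeeping (path NULL when S has no off-diagonal signal)
ebic_path_core <- function(S, n, gamma, n_lambda, lambda_min_ratio) {
  p <- ncol(S)
  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax == 0) return(list(K = diag(p), lambda = NA_real_, path = NULL))
  lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                     length.out = n_lambda))
  fit <- .glasso_path(S, lambdas, 1e-6, 500)
  if (!all(fit$converged))
    stop("graphical lasso failed to converge at lambda = ",
         format(lambdas[which(!fit$converged)[1]]))
  L <- (n / 2) * (fit$logdet - fit$trSK)
  ebic <- -2 * L + fit$ecount * log(n) + 4 * fit$ecount * gamma * log(p)
  # refit scoring makes every lambda with the same support score equally:
  # break ties toward the sparser support, then toward the smallest
  # penalty within it so the reported weights carry minimal shrinkage
  tol <- 1e-6 * max(1, abs(min(ebic)))
  cand <- which(ebic <= min(ebic) + tol)
  cand <- cand[fit$ecount[cand] == min(fit$ecount[cand])]
  sel <- max(cand)                     # lambdas decrease along the path
  list(K = fit$K[, , sel], lambda = lambdas[sel],
       path = structure(list(lambdas = lambdas, ebic = ebic,
                             loglik = L, ecount = fit$ecount),
                        class = "rf_penalty_path"))
}

#' Zero-order association network
#'
#' Copies the off-diagonals of a correlation matrix as edge weights, with
#' no selection or regularization.
#'
#' @param S correlation matrix or `rf_mixed_cor`.
#' @param labels,node_types optional node metadata.
#' @return An [new_network()] of kind `"zero_order"`.
#' @export
association_network <- function(S, labels = NULL, node_types = NULL) {
  n <- NA_integer_
  if (inherits(S, "rf_mixed_cor")) {
    n <- min(S$pair_n[upper.tri(S$pair_n)])
    S <- S$values
  }
  S <- as.matrix(S)
  if (is.null(labels)) labels <- colnames(S)
  W <- S
  diag(W) <- 0
  new_network(W, labels, node_types, "zero_order", list(n = n))
}

#' Remove a node without re-estimation
#'
#' Deletes a node's row and column, keeping every remaining edge exactly
#' as estimated in the larger model. Applied to a network that includes a
#' distress (criterion) node, the result is the distress-corrected
#' subnetwork: edges conditioned on the removed variable, which the
#' removed variable itself no longer appears in.
#'
#' @param net an [new_network()] object.
#' @param node node label to drop.
#' @return The reduced network.
#' @export
remove_node <- function(net, node) {
  stopifnot(inherits(net, "rf_network"))
  idx <- match(node, net$labels)
  if (is.na(idx)) stop("unknown node '", node, "'")
  keep <- setdiff(seq_along(net$labels), idx)
  meta <- net$meta
  meta$removed_node <- node
  meta$precision <- NULL
  new_network(net$weights[keep, keep, drop = FALSE], net$labels[keep],
              net$node_types[keep], net$kind, meta)
}
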