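# Shared fixtures and independent oracles, all built in code.

# chain graph partial-correlation matrix: p nodes, r on the off-diagonal
chain_partials <- function(p, r) {
  P <- matrix(0, p, p)
  for (i in seq_len(p - 1)) P[i, i + 1] <- P[i + 1, i] <- r
  P
}

# random sparse valid partial matrix (rescaled until the induced
# precision is positive definite)
rand_partials <- function(p, density = 0.3, scale = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    P <- matrix(0, p, p)
    up <- which(upper.tri(P))
    on <- sample(up, max(1, round(density * length(up))))
    P[on] <- runif(length(on), -scale, scale)
    P <- P + t(P)
    if (min(eigen(diag(p) - P, symmetric = TRUE,
                  only.values = TRUE)$values) > 0.05)
      return(P)
    scale <- scale * 0.8
  }
}

# random sparse weighted network
rand_net <- function(p, density = 0.4, seed = 1) {
  set.seed(seed)
  W <- matrix(0, p, p)
  up <- which(upper.tri(W))
  on <- sample(up, max(1, round(density * length(up))))
  W[on] <- runif(length(on), -0.6, 0.6)
  W <- W + t(W)
  new_network(W, paste0("n", seq_len(p)))
}

# all-pairs shortest distances by Floyd-Warshall (alternative-algorithm
# oracle for the Dijkstra implementation)
floyd_warshall <- function(net) {
  D <- 1 / abs(net$weights)
  diag(D) <- 0
  p <- ncol(D)
  for (k in seq_len(p))
    for (i in seq_len(p))
      for (j in seq_len(p))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# projected-gradient minimizer of the penalized negative log-likelihood
# -log det K + tr(SK) + lam * sum_offdiag |K| (optimization oracle)
pg_glasso <- function(S, lam, iters = 50000, step = 5e-4) {
  p <- ncol(S)
  K <- diag(p)
  for (i in seq_len(iters)) {
    G <- -solve(K) + S
    K2 <- K - step * G
    off <- K2 - diag(diag(K2))
    off <- sign(off) * pmax(abs(off) - step * lam, 0)
    K2 <- off + diag(diag(K2))
    e <- eigen(K2, symmetric = TRUE)
    K <- e$vectors %*% (pmax(e$values, 1e-6) * t(e$vectors))
  }
  K
}

glasso_objective <- function(K, S, lam) {
  -determinant(K)$modulus[1] + sum(S * K) +
    lam * sum(abs(K - diag(diag(K))))
}

# support-restricted Gaussian MLE by direct numerical optimization over
# the free precision entries (independent oracle for the EBIC refit
# likelihood; non-PD iterates repelled by an infinite objective)
constrained_mle <- function(S, support) {
  p <- ncol(S)
  diag(support) <- FALSE
  free <- which(upper.tri(S) & support)
  build <- function(par) {
    K <- matrix(0, p, p)
    diag(K) <- par[seq_len(p)]
    K[free] <- par[-seq_len(p)]
    K + t(K) - diag(diag(K))
  }
  obj <- function(par) {
    K <- build(par)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    -(2 * sum(log(diag(ch))) - sum(S * K))
  }
  fit <- optim(c(rep(1, p), rep(0, length(free))), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  build(fit$par)
}

# small two-group all-continuous generator used across comparison tests
continuous_config <- function(Pa, Pb, n_a, n_b, seed) {
  p <- ncol(Pa)
  generator_config(n_a, n_b, paste0("v", seq_len(p)),
                   rep("continuous", p), Pa, Pb, seed = seed)
}
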