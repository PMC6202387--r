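test_that("glasso closed forms: full shrinkage and the unpenalized p = 2 fit", {
  set.seed(201)
  A <- matrix(rnorm(16), 4)
  S <- cov2cor(crossprod(A) + diag(4))
  K <- glasso_fit(S, max(abs(S[upper.tri(S)])) + 1e-12)
  expect_true(all(K[upper.tri(K)] == 0))
  S2 <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(glasso_fit(S2, 0, tol = 1e-8), solve(S2), tolerance = 1e-6)
})

test_that("glasso attains the penalized objective of a projected-gradient oracle", {
  set.seed(202)
  A <- matrix(rnorm(16), 4)
  S <- cov2cor(crossprod(A) + diag(4))
  K <- glasso_fit(S, 0.1, tol = 1e-8)
  K_pg <- pg_glasso(S, 0.1, iters = 60000)
  expect_lt(abs(glasso_objective(K, S, 0.1) -
                glasso_objective(K_pg, S, 0.1)), 1e-4)
  expect_lte(glasso_objective(K, S, 0.1),
             glasso_objective(K_pg, S, 0.1) + 1e-6)
})

test_that("precision standardization matches the textbook partial correlations", {
  expect_equal(precision_to_partials(diag(c(2, 3, 4))), matrix(0, 3, 3))
  S2 <- matrix(c(1, 0.45, 0.45, 1), 2)
  expect_equal(precision_to_partials(solve(S2))[1, 2], 0.45,
               tolerance = 1e-12)
  # 3x3: recursive formula r_12.3 = (r12 - r13 r23)/sqrt((1-r13^2)(1-r23^2))
  set.seed(203)
  A <- matrix(rnorm(9), 3)
  S <- cov2cor(crossprod(A) + diag(3))
  W <- precision_to_partials(solve(S))
  rec <- (S[1, 2] - S[1, 3] * S[2, 3]) /
    sqrt((1 - S[1, 3]^2) * (1 - S[2, 3]^2))
  expect_equal(W[1, 2], rec, tolerance = 1e-10)
  expect_error(precision_to_partials(diag(c(1, -1, 1))), "positive")
})

test_that("unregularized partials from the glasso equal direct inversion", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- sample(3:4, 1)
    A <- matrix(rnorm(p * p), p)
    S <- cov2cor(crossprod(A) + diag(p))
    expect_equal(precision_to_partials(glasso_fit(S, 0, tol = 1e-9)),
                 precision_to_partials(solve(S)), tolerance = 1e-6)
  }
})

test_that("EBIC selection returns an empty network for independent data", {
  fit <- ebic_glasso_network(diag(5), n = 1000)
  expect_equal(sum(fit$network$weights != 0), 0)
  expect_equal(fit$network$kind, "regularized_partial")
})

test_that("EBIC selection recovers the chain support at n = 5000", {
  P <- chain_partials(6, 0.35)
  cfg <- continuous_config(P, P, n_a = 5000, n_b = 10, seed = 204)
  X <- generate_group(cfg, "a")$values
  fit <- ebic_glasso_network(cor(X), n = 5000, gamma = 0.5)
  support <- fit$network$weights != 0
  expect_identical(unname(support), P != 0)
})

test_that("the selected lambda is the EBIC argmin under independent re-scoring", {
  P <- rand_partials(5, density = 0.5, seed = 205)
  cfg <- continuous_config(P, P, n_a = 800, n_b = 10, seed = 205)
  X <- generate_group(cfg, "a")$values
  S <- cor(X)
  fit <- ebic_glasso_network(S, n = 800, gamma = 0.5, n_lambda = 40)
  path <- fit$path
  expect_true(all(is.finite(path$ebic)))
  expect_true(all(diff(path$lambdas) < 0))
  # brute force: refit each lambda separately, recompute EBIC from
  # scratch with the support-restricted MLE from an independent
  # numerical optimizer
  rescore <- vapply(path$lambdas, function(l) {
    K <- glasso_fit(S, l)
    E <- sum(K[upper.tri(K)] != 0)
    Km <- constrained_mle(S, K != 0)
    L <- (800 / 2) * (determinant(Km)$modulus[1] - sum(S * Km))
    -2 * L + E * log(800) + 4 * E * 0.5 * log(5)
  }, 0)
  expect_equal(path$ebic, rescore, tolerance = 1e-3)
  # the selected lambda attains the independently recomputed minimum
  sel_idx <- match(fit$network$meta$lambda, path$lambdas)
  expect_lt(rescore[sel_idx], min(rescore) + 1e-3 * abs(min(rescore)))
  # selected model's precision is PD
  ev <- eigen(fit$network$meta$precision, symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("association networks copy the correlation matrix verbatim", {
  expect_equal(sum(association_network(diag(4))$weights != 0), 0)
  set.seed(206)
  A <- matrix(rnorm(16), 4)
  S <- cov2cor(crossprod(A) + diag(4))
  dimnames(S) <- list(letters[1:4], letters[1:4])
  net <- association_network(S)
  expect_equal(net$kind, "zero_order")
  W <- net$weights
  diag(W) <- 1
  expect_equal(W, S, tolerance = 1e-12)
})

test_that("node removal keeps the remaining edges of the larger model", {
  W <- matrix(0, 3, 3, dimnames = list(c("x", "y", "g"), c("x", "y", "g")))
  W["x", "y"] <- W["y", "x"] <- 0.25
  W["y", "g"] <- W["g", "y"] <- -0.4
  net <- new_network(W)
  red <- remove_node(net, "g")
  expect_equal(red$labels, c("x", "y"))
  expect_equal(red$weights["x", "y"], 0.25)
  expect_error(remove_node(net, "nope"), "unknown")
  # removing an isolated node changes nothing else
  W2 <- rbind(cbind(W, iso = 0), iso = 0)
  net2 <- new_network(W2)
  expect_equal(remove_node(net2, "iso")$weights, W)
})

test_that("conditioning on a common cause is not the same as marginalizing it", {
  # distress as a strong common cause of weakly negatively coupled factors:
  # the factor-only network shows positive edges, while the corrected
  # network (node removal from the larger fit) keeps the negative ones
  labels <- c("r1", "r2", "r3", "gd")
  P <- matrix(0, 4, 4, dimnames = list(labels, labels))
  P[1, 2] <- P[2, 1] <- -0.15
  P[1, 4] <- P[4, 1] <- 0.5
  P[2, 4] <- P[4, 2] <- 0.5
  P[3, 4] <- P[4, 3] <- 0.45
  cfg <- generator_config(4000, 10, labels, rep("continuous", 4), P, P,
                          node_roles = c(rep("resilience_factor", 3),
                                         "distress"), seed = 207)
  X <- generate_group(cfg, "a")$values
  full <- ebic_glasso_network(cor(X), n = 4000)$network
  corrected <- remove_node(full, "gd")
  rf_only <- ebic_glasso_network(cor(X[, 1:3]), n = 4000)$network
  expect_gt(rf_only$weights["r1", "r2"], 0)
  expect_lt(corrected$weights["r1", "r2"], 0)
  expect_gt(max(abs(corrected$weights - rf_only$weights)), 0.05)
})
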