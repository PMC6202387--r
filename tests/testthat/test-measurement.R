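discretize <- function(z, cuts) findInterval(z, cuts)

test_that("polychoric recovers the latent correlation", {
  set.seed(101)
  n <- 10000
  z1 <- rnorm(n)
  z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(n)
  x <- discretize(z1, c(-0.5, 0.5))
  y <- discretize(z2, c(-0.5, 0.5))
  est <- estimate_polychoric(x, y)
  expect_lt(abs(est - 0.5), 0.03)
  # grid-search oracle over the same two-step likelihood at 1e-3 steps
  tab <- table(factor(x), factor(y))
  tx <- qnorm(cumsum(rowSums(tab))[-nrow(tab)] / n)
  ty <- qnorm(cumsum(colSums(tab))[-ncol(tab)] / n)
  grid <- seq(-0.999, 0.999, by = 1e-3)
  ll <- vapply(grid, function(r)
    sum(tab * log(pmax(rfnet:::.bvn_cell_probs(tx, ty, r), 1e-12))), 0)
  expect_lt(abs(est - grid[which.max(ll)]), 2e-3)
  # independence and perfect concordance boundaries
  expect_lt(abs(estimate_polychoric(x, discretize(rnorm(n), c(-0.5, 0.5)))),
            0.03)
  x3 <- discretize(rnorm(300), c(-0.8, 0.6))
  expect_gte(estimate_polychoric(x3, x3), 0.99)
})

test_that("polyserial recovers the latent correlation", {
  set.seed(102)
  n <- 10000
  x <- rnorm(n)
  expect_gte(estimate_polyserial(x, as.integer(x > median(x))), 0.97)
  expect_lt(abs(estimate_polyserial(x, discretize(rnorm(n), 0))), 0.03)
  z <- -0.4 * x + sqrt(1 - 0.16) * rnorm(n)
  y <- discretize(z, c(-0.7, 0.4))
  expect_lt(abs(estimate_polyserial(x, y) - (-0.4)), 0.03)
})

test_that("polychoric/polyserial preconditions are enforced", {
  expect_error(estimate_polychoric(rep(1, 50), rbinom(50, 1, 0.5)),
               "categories")
  expect_error(estimate_polychoric(0:1, 0:1), "n >= 10")
  expect_error(estimate_polyserial(rep(2, 50), rbinom(50, 1, 0.5)),
               "constant")
})

test_that("auto correlation matrix dispatches per type pair", {
  set.seed(103)
  n <- 400
  X <- cbind(c1 = rnorm(n), c2 = rnorm(n), b1 = rbinom(n, 1, 0.4))
  tab <- study_table(X, rep("g", n),
                     c("continuous", "continuous", "binary"))
  mc <- auto_correlation_matrix(tab)
  expect_equal(mc$method[1, 2], "pearson")
  expect_equal(mc$method[1, 3], "polyserial")
  expect_equal(mc$values[1, 2], cor(X[, 1], X[, 2]), tolerance = 1e-12)
  expect_equal(diag(mc$values), c(c1 = 1, c2 = 1, b1 = 1))
  tab2 <- study_table(cbind(o1 = rbinom(n, 1, 0.5), o2 = rbinom(n, 1, 0.5)),
                      rep("g", n), c("binary", "binary"))
  expect_equal(auto_correlation_matrix(tab2)$method[1, 2], "polychoric")
})

test_that("listwise and pairwise estimates agree under MCAR missingness", {
  P <- rand_partials(5, density = 0.5, seed = 104)
  cfg <- continuous_config(P, P, n_a = 2000, n_b = 10, seed = 104)
  X <- generate_group(cfg, "a")$values
  set.seed(105)
  X[matrix(runif(length(X)) < 0.15, nrow(X))] <- NA
  tab <- study_table(X, rep("g", nrow(X)), rep("continuous", 5))
  pw <- auto_correlation_matrix(tab, "pairwise")$values
  lw <- auto_correlation_matrix(tab, "listwise")$values
  up <- upper.tri(pw)
  expect_gt(cor(pw[up], lw[up]), 0.95)
})

test_that("assembled matrices are PSD after the clipping repair", {
  # a deliberately inconsistent pairwise matrix
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- 0.9
  R[1, 3] <- R[3, 1] <- -0.9
  fixed <- rfnet:::psd_repair(R, matrix("", 3, 3), matrix(100, 3, 3))
  expect_true(fixed$psd_adjusted)
  ev <- eigen(fixed$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 1e-6 / 2)
  expect_equal(diag(fixed$values), rep(1, 3))
})

test_that("nonparanormal transform follows the truncated-ECDF formula", {
  # frozen independent step-by-step computation for input 1..5:
  # u = r/6, delta_5 = 0.0743507677613432, qnorm, rescale to unit sd
  oracle <- c(-1.291946655510471, -0.575216341314561, 0,
              0.575216341314561, 1.291946655510471)
  expect_equal(nonparanormal_transform(1:5), oracle, tolerance = 1e-12)
  set.seed(106)
  x <- rexp(500)^2
  y <- nonparanormal_transform(x)
  # monotone in the input ranks (non-strict at the truncated tails)
  expect_true(all(diff(y[order(x)]) >= 0))
  expect_gt(cor(x, y, method = "spearman"), 0.999)
  expect_equal(sd(y), 1, tolerance = 1e-9)
  z <- nonparanormal_transform(c(3, 3, 5, 9, 12))
  expect_equal(z[1], z[2])
  expect_error(nonparanormal_transform(rep(2, 10)), "distinct")
  # NAs preserved, remaining values still rank-monotone
  w <- nonparanormal_transform(c(1, NA, 2, 5))
  expect_true(is.na(w[2]) && !anyNA(w[-2]))
})

test_that("pooled-then-split differs from split-then-transform for shifted groups", {
  set.seed(107)
  vals <- c(rnorm(300, 0), rnorm(300, 1))
  tab <- study_table(matrix(vals, ncol = 1, dimnames = list(NULL, "v")),
                     rep(c("a", "b"), each = 300))
  pooled <- pooled_transform_then_split(tab)
  expect_identical(pooled$group, tab$group)
  split_a <- nonparanormal_transform(vals[1:300])
  expect_gt(max(abs(pooled$values[1:300, 1] - split_a)), 0.1)
  # identically distributed groups: the two orders converge
  same <- rnorm(2000)
  tab2 <- study_table(matrix(c(same, same), ncol = 1,
                             dimnames = list(NULL, "v")),
                      rep(c("a", "b"), each = 2000))
  p2 <- pooled_transform_then_split(tab2)$values[1:2000, 1]
  s2 <- nonparanormal_transform(same)
  expect_lt(mean(abs(p2 - s2)), 0.02)
  expect_gt(cor(p2, s2), 0.999)
})

test_that("one-factor ULS CFA solves the triad closed form", {
  R <- matrix(0.49, 3, 3)
  diag(R) <- 1
  fit <- fit_one_factor_cfa(R)
  expect_equal(unname(fit$loadings), rep(0.7, 3), tolerance = 1e-6)
  expect_lt(fit$fit_residual, 1e-10)
  # random perfectly-one-factor triads: lambda1 = sqrt(r12 r13 / r23)
  for (seed in 1:10) {
    set.seed(seed)
    lam <- runif(3, 0.3, 0.9)
    R3 <- tcrossprod(lam)
    diag(R3) <- 1
    fit3 <- fit_one_factor_cfa(R3)
    expect_equal(unname(fit3$loadings), lam, tolerance = 1e-6)
  }
  expect_equal(unname(fit_one_factor_cfa(diag(4))$loadings), rep(0, 4))
  expect_error(fit_one_factor_cfa(diag(2)), "3 items")
})

test_that("CFA loadings are recovered from simulated ordinal items", {
  set.seed(108)
  n <- 2000
  lam <- c(0.8, 0.7, 0.6, 0.5)
  f <- rnorm(n)
  items <- sapply(lam, function(l)
    discretize(l * f + sqrt(1 - l^2) * rnorm(n), c(-1, 0, 1)))
  colnames(items) <- paste0("i", 1:4)
  tab <- study_table(items, rep("g", n), rep("ordinal", 4),
                     rep("item", 4))
  poly <- auto_correlation_matrix(tab)
  fit <- fit_one_factor_cfa(poly)
  expect_lt(max(abs(fit$loadings - lam)), 0.07)
})

test_that("factor scores recover the latent factor from five 0.7 items", {
  set.seed(120)
  n <- 2000
  f <- rnorm(n)
  items <- sapply(rep(0.7, 5), function(l)
    discretize(l * f + sqrt(1 - l^2) * rnorm(n), c(-1, 0, 1)))
  colnames(items) <- paste0("i", 1:5)
  tab <- study_table(items, rep("g", n), rep("ordinal", 5),
                     rep("item", 5))
  fit <- fit_one_factor_cfa(auto_correlation_matrix(tab))
  sc <- factor_scores(fit, items)
  expect_gte(cor(sc, f), 0.85)
})

test_that("factor scores respect symmetry, sign and missingness contracts", {
  set.seed(109)
  n <- 300
  f <- rnorm(n)
  items <- sapply(rep(0.7, 5), function(l)
    discretize(l * f + sqrt(1 - l^2) * rnorm(n), c(-0.5, 0.5)))
  model <- structure(list(loadings = rep(0.6, 5), thresholds = NULL,
                          fit_residual = 0), class = "rf_factor_model")
  sc <- factor_scores(model, items)
  # equal loadings: score is a positive affine map of the standardized
  # item sum (Pearson r exactly 1)
  expect_equal(cor(sc, rowSums(scale(items))), 1, tolerance = 1e-12)
  # flipped loadings + reversed items flip the score sign
  model_neg <- model
  model_neg$loadings <- -model$loadings
  sc_neg <- factor_scores(model_neg, max(items) - items)
  expect_equal(sc_neg, sc, tolerance = 1e-9)
  sc_flip <- factor_scores(model_neg, items)
  expect_equal(sc_flip, -sc, tolerance = 1e-9)
  items_na <- items
  items_na[1, ] <- NA
  items_na[2, 1:2] <- NA
  sc_na <- factor_scores(model, items_na)
  expect_true(is.na(sc_na[1]))
  expect_false(is.na(sc_na[2]))
})

test_that("restricted-range dichotomization codes the protective mass point 1", {
  expect_equal(dichotomize_restricted(c(0, 0, 1, 2), protective = 0),
               c(1, 1, 0, 0))
  # default: modal value is the protective level
  x <- c(1, 1, 1, 0, 2, NA)
  d <- dichotomize_restricted(x)
  expect_equal(d, c(1, 1, 1, 0, 0, NA))
  expect_error(dichotomize_restricted(c(1, 1, 1), protective = 1),
               "degenerate")
  expect_error(dichotomize_restricted(c(0, 1, 2), protective = 9),
               "outside")
})
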