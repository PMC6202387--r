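# Bootstrap accuracy of edge weights and case-dropping stability of
# centrality orders.

#' Nonparametric edge-weight bootstrap (accuracy)
#'
#' Resamples persons with replacement and re-estimates the network per
#' replicate. Per edge it reports the regularized point estimate, the
#' bootstrap median of the regularized replicate weights, and a 95%
#' percentile confidence interval computed from the support-refit
#' (unpenalized, support-restricted MLE) replicate weights — the refit
#' keeps lasso shrinkage from biasing the interval location while the
#' interval width still reflects sampling and selection variability. The
#' width of an edge's interval indicates how accurately that edge is
#' estimated.
#'
#' @param table a single-group [study_table()].
#' @param estimator an [estimator_config()].
#' @param n_boot bootstrap replicates (>= 100; the reference design uses
#'   2000).
#' @param seed integer seed.
#' @return Object of class `rf_boot_accuracy`: data.frame `edges` with
#'   point estimates (`estimate` regularized, `refit_estimate`
#'   unshrunk), CI bounds and bootstrap median per edge, plus the
#'   replicate weight matrices.
#' @export
edge_bootstrap <- function(table, estimator = estimator_config(),
                           n_boot = 2000, seed = 1L) {
  stopifnot(inherits(table, "rf_study_table"))
  if (n_boot < 100) stop("n_boot must be >= 100")
  n <- nrow(table$values)
  w0 <- estimate_weights_refit(table$values, table$var_types,
                               table$var_roles, estimator)
  up <- upper.tri(w0$shrunk)
  labs <- colnames(table$values)
  edge_names <- outer(labs, labs, paste, sep = "--")[up]
  reps <- reps_refit <- matrix(NA_real_, n_boot, sum(up))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  redraws <- 0L
  max_redraws <- max(1L, ceiling(0.01 * n_boot))
  b <- 0L
  while (b < n_boot) {
    idx <- sample(n, replace = TRUE)
    w <- tryCatch(
      estimate_weights_refit(table$values[idx, , drop = FALSE],
                             table$var_types, table$var_roles, estimator),
      error = function(e) e)
    if (inherits(w, "error")) {
      redraws <- redraws + 1L
      if (redraws > max_redraws)
        stop("too many failed bootstrap replicates: ",
             conditionMessage(w))
      next
    }
    b <- b + 1L
    reps[b, ] <- w$shrunk[up]
    reps_refit[b, ] <- w$refit[up]
  }
  ci <- apply(reps_refit, 2, quantile, c(0.025, 0.975))
  structure(list(
    edges = data.frame(edge = edge_names, estimate = w0$shrunk[up],
                       refit_estimate = w0$refit[up],
                       lower = ci[1, ], upper = ci[2, ],
                       boot_median = apply(reps, 2, stats::median),
                       row.names = NULL),
    replicates = reps, replicates_refit = reps_refit,
    n_boot = n_boot, seed = seed, redraws = redraws),
    class = "rf_boot_accuracy")
}

#' Case-dropping subset bootstrap (centrality stability)
#'
#' For each drop proportion, repeatedly re-estimates the network on a
#' random person subset and correlates (Spearman) the subset node
#' strength and expected influence with the full-sample values. The
#' stability coefficient per metric is the largest drop proportion at
#' which the correlation stays >= 0.7 in at least 95% of replicates (and
#' at every smaller proportion on the grid).
#'
#' @param table a single-group [study_table()].
#' @param estimator an [estimator_config()].
#' @param drop_grid drop proportions within (0, 0.9].
#' @param n_boot subsets per grid point.
#' @param seed integer seed.
#' @return Object of class `rf_boot_stability`: data.frame `curve`
#'   (per drop proportion: mean and the 5% quantile of the correlations
#'   per metric) and `stability_coefficient` per metric.
#' @export
case_dropping_stability <- function(table, estimator = estimator_config(),
                                    drop_grid = seq(0.1, 0.7, by = 0.1),
                                    n_boot = 2000, seed = 1L) {
  stopifnot(inherits(table, "rf_study_table"))
  if (any(drop_grid <= 0 | drop_grid > 0.9))
    stop("drop_grid must lie within (0, 0.9]")
  drop_grid <- sort(drop_grid)
  n <- nrow(table$values)
  p <- ncol(table$values)
  w0 <- estimate_weights(table$values, table$var_types, table$var_roles,
                         estimator)
  net0 <- new_network(w0, colnames(table$values))
  s0 <- node_strength(net0)
  e0 <- expected_influence(net0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- list()
  pass <- list(strength = logical(0), ei = logical(0))
  for (d in drop_grid) {
    m <- round((1 - d) * n)
    if (m < p + 10) {
      warning("drop proportion ", d, " leaves only ", m,
              " persons; skipped")
      next
    }
    cs <- ce <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample(n, m)
      w <- tryCatch(
        estimate_weights(table$values[idx, , drop = FALSE],
                         table$var_types, table$var_roles, estimator),
        error = function(e) NULL)
      if (is.null(w)) next
      net <- new_network(w, colnames(table$values))
      cs[b] <- suppressWarnings(
        cor(s0, node_strength(net), method = "spearman"))
      ce[b] <- suppressWarnings(
        cor(e0, expected_influence(net), method = "spearman"))
    }
    rows[[length(rows) + 1]] <- data.frame(
      drop = d,
      strength_mean = mean(cs, na.rm = TRUE),
      strength_q05 = quantile(cs, 0.05, na.rm = TRUE, names = FALSE),
      ei_mean = mean(ce, na.rm = TRUE),
      ei_q05 = quantile(ce, 0.05, na.rm = TRUE, names = FALSE))
    pass$strength <- c(pass$strength,
                       mean(cs >= 0.7, na.rm = TRUE) >= 0.95)
    pass$ei <- c(pass$ei, mean(ce >= 0.7, na.rm = TRUE) >= 0.95)
  }
  curve <- do.call(rbind, rows)
  cs_coef <- function(ok) {
    ok[is.na(ok)] <- FALSE
    if (!length(ok) || !ok[1]) return(0)
    run <- which(!cumsum(!ok))        # leading TRUE run
    max(curve$drop[run])
  }
  structure(list(curve = curve,
                 stability_coefficient = c(
                   strength = cs_coef(pass$strength),
                   expected_influence = cs_coef(pass$ei)),
                 n_boot = n_boot, seed = seed),
            class = "rf_boot_stability")
}
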