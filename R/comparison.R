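#' Network estimator settings
#'
#' Bundles the settings shared by every estimation in a comparison or
#' bootstrap: EBIC hyperparameter, penalty-path geometry, and the
#' missing-data deletion mode.
#'
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda,lambda_min_ratio penalty path geometry.
#' @param deletion `"pairwise"` or `"listwise"`.
#' @return Object of class `rf_estimator_config`.
#' @export
estimator_config <- function(gamma = 0.5, n_lambda = 100,
                             lambda_min_ratio = 0.01,
                             deletion = c("pairwise", "listwise")) {
  structure(list(gamma = gamma, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio,
                 deletion = match.arg(deletion)),
            class = "rf_estimator_config")
}

#' Estimate a group's regularized network from a study table
#'
#' Convenience stage: auto-typed correlation matrix, then EBIC graphical
#' lasso.
#'
#' @param table a single-group [study_table()].
#' @param estimator an [estimator_config()].
#' @return List with `network` and `path` as in [ebic_glasso_network()].
#' @export
estimate_network <- function(table, estimator = estimator_config()) {
  stopifnot(inherits(table, "rf_study_table"))
  S <- auto_correlation_matrix(table, estimator$deletion)
  ebic_glasso_network(S, gamma = estimator$gamma,
                      n_lambda = estimator$n_lambda,
                      lambda_min_ratio = estimator$lambda_min_ratio,
                      node_types = unname(table$var_types))
}

# weights matrix for one group's raw value matrix; shared by the
# permutation and bootstrap loops. Complete all-continuous data take a
# lean path (the Pearson matrix of complete data is already PSD, so the
# repair step is a no-op there); everything else runs through the full
# mixed-correlation machinery.
estimate_weights <- function(values, var_types, var_roles, estimator) {
  if (all(var_types == "continuous") && !anyNA(values)) {
    S <- cor(values)
    core <- ebic_path_core(S, nrow(values), estimator$gamma,
                           estimator$n_lambda, estimator$lambda_min_ratio)
    W <- precision_to_partials(core$K)
    dimnames(W) <- list(colnames(values), colnames(values))
    return(W)
  }
  tb <- study_table(values, rep("g", nrow(values)), var_types, var_roles)
  estimate_network(tb, estimator)$network$weights
}

# shrunk and support-refit weights from one estimation (the refit is the
# unpenalized MLE restricted to the selected support; bootstrap CIs use
# it so lasso shrinkage does not bias the interval location)
estimate_weights_refit <- function(values, var_types, var_roles,
                                   estimator) {
  if (all(var_types == "continuous") && !anyNA(values)) {
    S <- cor(values)
    n <- nrow(values)
  } else {
    tb <- study_table(values, rep("g", nrow(values)), var_types, var_roles)
    mc <- auto_correlation_matrix(tb, estimator$deletion)
    S <- mc$values
    n <- min(mc$pair_n[upper.tri(mc$pair_n)])
  }
  core <- ebic_path_core(S, n, estimator$gamma, estimator$n_lambda,
                         estimator$lambda_min_ratio)
  W <- precision_to_partials(core$K)
  supp <- matrix(as.integer(core$K != 0), ncol(S))
  ref <- .glasso_refit(S, supp, 1e-6, 500)
  Wref <- precision_to_partials(ref$K)
  dimnames(W) <- dimnames(Wref) <- list(colnames(values), colnames(values))
  list(shrunk = W, refit = Wref)
}

comparison_stats <- function(wA, wB) {
  d <- abs(wA - wB)[upper.tri(wA)]
  list(edge = d, M = max(d),
       dS = abs(sum(abs(wA[upper.tri(wA)])) - sum(abs(wB[upper.tri(wB)]))),
       dEI = abs(sum(wA[upper.tri(wA)]) - sum(wB[upper.tri(wB)])))
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p raw p-values in (0, 1].
#' @param alpha family-wise error target for the rejection flags.
#' @return List with `adjusted` p-values (monotone, capped at 1) and
#'   logical `reject` flags.
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  adjusted <- p.adjust(p, method = "holm")
  list(adjusted = adjusted, reject = adjusted <= alpha)
}

#' Permutation comparison of two group networks
#'
#' Estimates each group's EBIC graphical-lasso network under a shared
#' estimator configuration and tests four statistics against their
#' permutation nulls: the maximal absolute edge difference `M` (network
#' structure invariance), the absolute global strength difference, the
#' absolute global expected influence difference, and every per-edge
#' absolute difference (Holm-Bonferroni corrected). Each permutation
#' reshuffles the group labels preserving group sizes and re-runs the
#' full estimator for both pseudo-groups. P-values use
#' `(1 + #(perm >= observed)) / (1 + n_perm)`; the statistics are
#' absolute, so the tests are two-tailed by construction. Variables
#' should be transformed on the pooled sample beforehand
#' ([pooled_transform_then_split()]) so the groups are exchangeable.
#'
#' @param tableA,tableB single-group [study_table()]s over identical
#'   variables.
#' @param n_perm number of permutations (>= 20; the reference design uses
#'   5000).
#' @param estimator an [estimator_config()].
#' @param seed integer seed for the permutation stream.
#' @return Object of class `rf_comparison`: `observed` (M, dS, dEI,
#'   per-edge differences), `p_values` (m, strength, ei, per-edge raw and
#'   Holm-adjusted), the group networks, `n_perm`, `seed`, and the count
#'   of redrawn permutations.
#' @export
compare_networks <- function(tableA, tableB, n_perm = 5000,
                             estimator = estimator_config(), seed = 1L) {
  stopifnot(inherits(tableA, "rf_study_table"),
            inherits(tableB, "rf_study_table"))
  if (!identical(colnames(tableA$values), colnames(tableB$values)) ||
      !identical(unname(tableA$var_types), unname(tableB$var_types)))
    stop("both tables must share the same variables and types")
  if (n_perm < 20) stop("n_perm must be >= 20")
  labs <- colnames(tableA$values)
  nA <- nrow(tableA$values)
  pooled <- rbind(tableA$values, tableB$values)
  wA <- estimate_weights(tableA$values, tableA$var_types,
                         tableA$var_roles, estimator)
  wB <- estimate_weights(tableB$values, tableB$var_types,
                         tableB$var_roles, estimator)
  obs <- comparison_stats(wA, wB)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_edges <- length(obs$edge)
  count_M <- count_S <- count_EI <- 0
  count_edge <- numeric(n_edges)
  redraws <- 0L
  max_redraws <- max(1L, ceiling(0.01 * n_perm))
  done <- 0L
  while (done < n_perm) {
    idx <- sample(nrow(pooled))
    st <- tryCatch({
      pA <- estimate_weights(pooled[idx[seq_len(nA)], , drop = FALSE],
                             tableA$var_types, tableA$var_roles, estimator)
      pB <- estimate_weights(pooled[idx[-seq_len(nA)], , drop = FALSE],
                             tableA$var_types, tableA$var_roles, estimator)
      comparison_stats(pA, pB)
    }, error = function(e) e)
    if (inherits(st, "error")) {
      redraws <- redraws + 1L
      if (redraws > max_redraws)
        stop("too many failed permutations (", redraws, "): last error: ",
             conditionMessage(st))
      next
    }
    done <- done + 1L
    count_M <- count_M + (st$M >= obs$M)
    count_S <- count_S + (st$dS >= obs$dS)
    count_EI <- count_EI + (st$dEI >= obs$dEI)
    count_edge <- count_edge + (st$edge >= obs$edge)
  }
  pval <- function(cnt) (1 + cnt) / (1 + n_perm)
  edge_names <- outer(labs, labs, paste, sep = "--")[upper.tri(diag(length(labs)))]
  p_edge <- stats::setNames(pval(count_edge), edge_names)
  holm <- holm_bonferroni(p_edge)
  edge_diff <- abs(wA - wB)
  structure(list(
    observed = list(M = obs$M, dS = obs$dS, dEI = obs$dEI,
                    edge_diff = edge_diff),
    p_values = list(m = pval(count_M), strength = pval(count_S),
                    ei = pval(count_EI), edges_raw = p_edge,
                    edges_holm = stats::setNames(holm$adjusted, edge_names)),
    networks = list(a = new_network(wA, labs, unname(tableA$var_types)),
                    b = new_network(wB, labs, unname(tableA$var_types))),
    structure_r = {
      a <- wA[upper.tri(wA)]; b <- wB[upper.tri(wB)]
      if (sd(a) > 0 && sd(b) > 0) cor(a, b) else NA_real_
    },
    n_perm = n_perm, seed = seed, redraws = redraws),
    class = "rf_comparison")
}

#' @export
print.rf_comparison <- function(x, ...) {
  cat("Two-group network comparison (", x$n_perm, " permutations)\n",
      sep = "")
  cat(sprintf("  structure correlation r = %.3f\n", x$structure_r))
  cat(sprintf("  invariance M  = %.3f  p = %.3g\n", x$observed$M,
              x$p_values$m))
  cat(sprintf("  strength  dS  = %.3f  p = %.3g\n", x$observed$dS,
              x$p_values$strength))
  cat(sprintf("  EI        dEI = %.3f  p = %.3g\n", x$observed$dEI,
              x$p_values$ei))
  sig <- names(which(x$p_values$edges_holm <= 0.05))
  cat("  Holm-significant edges:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}
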