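# Orchestration of the three-network design: RF-only networks, RF +
# distress networks, and distress-corrected subnetworks, each compared
# across the two groups, plus pathways, centrality, predictability,
# robustness and the deletion-mode sensitivity check.

#' Full-analysis settings
#'
#' @param estimator an [estimator_config()].
#' @param n_perm permutations per comparison.
#' @param n_boot bootstrap replicates (accuracy and stability each).
#' @param drop_grid case-dropping proportions.
#' @param alpha significance level used in reports.
#' @param seed master seed (mandatory for the stochastic stages).
#' @param run_bootstraps run the robustness stage (the slowest stage).
#' @param output_dir optional directory; when given, every artifact is
#'   written there (CSV/JSON/GraphML) with a manifest.
#' @return Object of class `rf_pipeline_config`.
#' @export
pipeline_config <- function(estimator = estimator_config(),
                            n_perm = 5000, n_boot = 2000,
                            drop_grid = seq(0.1, 0.7, by = 0.1),
                            alpha = 0.05, seed = 1L,
                            run_bootstraps = TRUE,
                            output_dir = NULL) {
  structure(list(estimator = estimator, n_perm = n_perm, n_boot = n_boot,
                 drop_grid = drop_grid, alpha = alpha,
                 seed = as.integer(seed),
                 run_bootstraps = run_bootstraps,
                 output_dir = output_dir),
            class = "rf_pipeline_config")
}

#' Run the complete two-group network analysis
#'
#' Executes, on a two-group study table whose roles mark the resilience
#' factors and the distress variable:
#' (a) RF-only networks per group + permutation comparison;
#' (b) RF + distress networks per group + comparison;
#' (c) distress-corrected RF subnetworks ([remove_node()] on (b), never
#' re-estimated) + comparison;
#' (d) shortest pathways from every RF to distress per group;
#' (e) centrality and nodewise predictability per group and design;
#' (f) edge bootstrap and case-dropping stability per group (optional);
#' (g) a sensitivity rerun with listwise deletion and the structure
#' correlation between deletion modes.
#'
#' The continuous columns are nonparanormal-transformed on the pooled
#' sample first. Deterministic given `config$seed`.
#'
#' @param table a two-group [study_table()] with a single
#'   `"distress"`-role column.
#' @param config a [pipeline_config()].
#' @return Object of class `rf_analysis` (a named list of stage results).
#' @export
run_full_analysis <- function(table, config = pipeline_config()) {
  stopifnot(inherits(table, "rf_study_table"),
            inherits(config, "rf_pipeline_config"))
  if (sum(table$var_roles == "distress") != 1)
    stop("the table must contain exactly one distress-role column")
  gd <- names(table$var_roles)[table$var_roles == "distress"]
  groups <- levels(table$group)
  if (length(groups) != 2) stop("exactly two groups required")

  prepared <- pooled_transform_then_split(table)
  rf_table <- subset_vars(prepared, "resilience_factor")
  full_table <- subset_vars(
    prepared, c(names(prepared$var_roles)[prepared$var_roles ==
                                            "resilience_factor"], gd))
  split2 <- function(tb) list(a = table_group(tb, groups[1]),
                              b = table_group(tb, groups[2]))
  rf <- split2(rf_table)
  fl <- split2(full_table)
  est <- config$estimator

  networks <- list()
  for (g in c("a", "b")) {
    networks[[paste0("rf_only_", g)]] <- estimate_network(rf[[g]], est)$network
    networks[[paste0("with_gd_", g)]] <- estimate_network(fl[[g]], est)$network
    networks[[paste0("gd_corrected_", g)]] <-
      remove_node(networks[[paste0("with_gd_", g)]], gd)
  }

  comparisons <- list(
    rf_only = compare_networks(rf$a, rf$b, config$n_perm, est,
                               seed = config$seed + 101L),
    with_gd = compare_networks(fl$a, fl$b, config$n_perm, est,
                               seed = config$seed + 202L))
  # design (c): the corrected networks come from (b) by node removal;
  # its permutation null removes the node from each permuted fit too
  comparisons$gd_corrected <- compare_corrected(
    fl$a, fl$b, gd, config$n_perm, est, seed = config$seed + 303L)

  paths <- list(
    a = shortest_pathways(networks$with_gd_a, target = gd),
    b = shortest_pathways(networks$with_gd_b, target = gd))

  centrality <- list(
    rf_only = list(a = centrality_report(networks$rf_only_a, rf$a,
                                         est$gamma),
                   b = centrality_report(networks$rf_only_b, rf$b,
                                         est$gamma)),
    gd_corrected = list(a = centrality_report(networks$gd_corrected_a),
                        b = centrality_report(networks$gd_corrected_b)))

  robustness <- NULL
  if (config$run_bootstraps) {
    robustness <- list(
      accuracy = list(
        a = edge_bootstrap(rf$a, est, config$n_boot,
                           seed = config$seed + 404L),
        b = edge_bootstrap(rf$b, est, config$n_boot,
                           seed = config$seed + 505L)),
      stability = list(
        a = case_dropping_stability(rf$a, est, config$drop_grid,
                                    config$n_boot,
                                    seed = config$seed + 606L),
        b = case_dropping_stability(rf$b, est, config$drop_grid,
                                    config$n_boot,
                                    seed = config$seed + 707L)))
  }

  # sensitivity: listwise vs pairwise deletion
  est_lw <- estimator_config(est$gamma, est$n_lambda,
                             est$lambda_min_ratio, "listwise")
  sens <- lapply(c(a = "a", b = "b"), function(g) {
    lw <- estimate_network(rf[[g]], est_lw)$network
    structure_correlation(networks[[paste0("rf_only_", g)]], lw)
  })

  res <- structure(list(networks = networks, comparisons = comparisons,
                        paths = paths, centrality = centrality,
                        robustness = robustness,
                        sensitivity = sens, groups = groups,
                        distress = gd, config = config),
                   class = "rf_analysis")
  if (!is.null(config$output_dir)) write_analysis(res, table)
  res
}

# comparison for the corrected design: estimate the full model per
# (pseudo-)group, drop the distress node, compare the remainders
compare_corrected <- function(tableA, tableB, gd, n_perm, estimator,
                              seed) {
  drop_gd <- function(w) {
    keep <- setdiff(colnames(w), gd)
    w[keep, keep]
  }
  nA <- nrow(tableA$values)
  pooled <- rbind(tableA$values, tableB$values)
  est_w <- function(values)
    drop_gd(estimate_weights(values, tableA$var_types, tableA$var_roles,
                             estimator))
  wA <- est_w(tableA$values)
  wB <- est_w(tableB$values)
  obs <- comparison_stats(wA, wB)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  count_M <- count_S <- count_EI <- 0
  count_edge <- numeric(length(obs$edge))
  redraws <- 0L; done <- 0L
  max_redraws <- max(1L, ceiling(0.01 * n_perm))
  while (done < n_perm) {
    idx <- sample(nrow(pooled))
    st <- tryCatch({
      pA <- est_w(pooled[idx[seq_len(nA)], , drop = FALSE])
      pB <- est_w(pooled[idx[-seq_len(nA)], , drop = FALSE])
      comparison_stats(pA, pB)
    }, error = function(e) e)
    if (inherits(st, "error")) {
      redraws <- redraws + 1L
      if (redraws > max_redraws) stop("too many failed permutations")
      next
    }
    done <- done + 1L
    count_M <- count_M + (st$M >= obs$M)
    count_S <- count_S + (st$dS >= obs$dS)
    count_EI <- count_EI + (st$dEI >= obs$dEI)
    count_edge <- count_edge + (st$edge >= obs$edge)
  }
  labs <- colnames(wA)
  pval <- function(cnt) (1 + cnt) / (1 + n_perm)
  edge_names <- outer(labs, labs, paste, sep = "--")[upper.tri(wA)]
  p_edge <- stats::setNames(pval(count_edge), edge_names)
  holm <- holm_bonferroni(p_edge)
  structure(list(
    observed = list(M = obs$M, dS = obs$dS, dEI = obs$dEI,
                    edge_diff = abs(wA - wB)),
    p_values = list(m = pval(count_M), strength = pval(count_S),
                    ei = pval(count_EI), edges_raw = p_edge,
                    edges_holm = stats::setNames(holm$adjusted, edge_names)),
    networks = list(a = new_network(wA, labs), b = new_network(wB, labs)),
    structure_r = {
      a <- wA[upper.tri(wA)]; b <- wB[upper.tri(wB)]
      if (sd(a) > 0 && sd(b) > 0) cor(a, b) else NA_real_
    },
    n_perm = n_perm, seed = seed, redraws = redraws),
    class = "rf_comparison")
}

#' Serialize a network to edge-list CSV and GraphML
#'
#' Writes `<path>.csv` (node_i, node_j, weight over nonzero edges),
#' `<path>.graphml`, and `<path>.json` holding the estimator metadata.
#'
#' @param net an [new_network()] object.
#' @param path path prefix (no extension).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "rf_network"))
  up <- which(upper.tri(net$weights) & net$weights != 0, arr.ind = TRUE)
  el <- data.frame(node_i = net$labels[up[, 1]],
                   node_j = net$labels[up[, 2]],
                   weight = net$weights[up])
  utils::write.csv(el, paste0(path, ".csv"), row.names = FALSE)
  g <- igraph::graph_from_adjacency_matrix(abs(net$weights) > 0,
                                           mode = "undirected")
  igraph::E(g)$weight <- net$weights[as.matrix(igraph::as_edgelist(
    g, names = FALSE))]
  igraph::write_graph(g, paste0(path, ".graphml"), format = "graphml")
  meta <- net$meta
  meta$precision <- NULL
  jsonlite::write_json(list(kind = net$kind, meta = meta),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

comparison_to_list <- function(cmp) {
  list(observed = list(M = cmp$observed$M, dS = cmp$observed$dS,
                       dEI = cmp$observed$dEI),
       structure_r = cmp$structure_r,
       p_values = list(m = cmp$p_values$m,
                       strength = cmp$p_values$strength,
                       ei = cmp$p_values$ei,
                       edges_holm = as.list(cmp$p_values$edges_holm)),
       n_perm = cmp$n_perm, seed = cmp$seed, redraws = cmp$redraws)
}

write_analysis <- function(res, raw_table) {
  dir.create(res$config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(res$config$output_dir, ...)
  for (nm in names(res$networks)) write_network(res$networks[[nm]], out(nm))
  for (nm in names(res$comparisons))
    jsonlite::write_json(comparison_to_list(res$comparisons[[nm]]),
                         out(paste0("comparison_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
  for (g in c("a", "b")) {
    pt <- res$paths[[g]]
    df <- pt$table
    df$route <- vapply(pt$sequences, paste, "", collapse = " -> ")
    utils::write.csv(df, out(paste0("paths_", g, ".csv")),
                     row.names = FALSE)
  }
  tmp <- tempfile(fileext = ".csv")
  write_study_table(raw_table, tmp)
  manifest <- list(
    input_md5 = unname(tools::md5sum(tmp)),
    n_per_group = as.list(table(raw_table$group)),
    settings = list(gamma = res$config$estimator$gamma,
                    n_lambda = res$config$estimator$n_lambda,
                    lambda_min_ratio = res$config$estimator$lambda_min_ratio,
                    deletion = res$config$estimator$deletion,
                    n_perm = res$config$n_perm,
                    n_boot = res$config$n_boot,
                    seed = res$config$seed))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
  unlink(c(tmp, paste0(tmp, ".meta.json")))
  invisible(res)
}

#' @export
print.rf_analysis <- function(x, ...) {
  cat("Two-group resilience-factor network analysis\n")
  cat("Groups:", paste(x$groups, collapse = " vs "), "| distress node:",
      x$distress, "\n\n")
  for (nm in names(x$comparisons)) {
    cmp <- x$comparisons[[nm]]
    cat(sprintf(
      "[%s] r = %.2f | M = %.3f (p = %.3g) | dS = %.3f (p = %.3g) | dEI = %.3f (p = %.3g)\n",
      nm, cmp$structure_r, cmp$observed$M, cmp$p_values$m,
      cmp$observed$dS, cmp$p_values$strength, cmp$observed$dEI,
      cmp$p_values$ei))
  }
  cat("\nDirect pathways to distress: group a:",
      sum(x$paths$a$table$direct), "| group b:",
      sum(x$paths$b$table$direct), "\n")
  cat("Deletion-mode sensitivity r: a =",
      format(x$sensitivity$a, digits = 3), ", b =",
      format(x$sensitivity$b, digits = 3), "\n")
  invisible(x)
}
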