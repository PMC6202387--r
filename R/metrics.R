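# Node-level and global network statistics, predictability, structure
# correlation, and shortest pathways.

#' Node strength: sum of absolute edge weights per node
#' @param net an [new_network()] object.
#' @return Named numeric vector.
#' @export
node_strength <- function(net) {
  stopifnot(inherits(net, "rf_network"))
  rowSums(abs(net$weights))
}

#' Expected influence: signed sum of edge weights per node
#' @param net an [new_network()] object.
#' @return Named numeric vector.
#' @export
expected_influence <- function(net) {
  stopifnot(inherits(net, "rf_network"))
  rowSums(net$weights)
}

#' Global strength: upper-triangle sum of absolute edge weights
#'
#' Each edge counts once, so global strength equals half the sum of node
#' strengths.
#' @param net an [new_network()] object.
#' @return Scalar.
#' @export
global_strength <- function(net) {
  stopifnot(inherits(net, "rf_network"))
  sum(abs(net$weights[upper.tri(net$weights)]))
}

#' Global expected influence: signed upper-triangle edge sum
#' @param net an [new_network()] object.
#' @return Scalar.
#' @export
global_expected_influence <- function(net) {
  stopifnot(inherits(net, "rf_network"))
  sum(net$weights[upper.tri(net$weights)])
}

#' Structure correlation between two networks
#'
#' Pearson correlation of the vectorized upper-triangle edge weights of
#' two networks over the same labelled nodes.
#'
#' @param netA,netB [new_network()] objects with identical labels.
#' @return Correlation; `NA` (with a warning) if either edge vector has
#'   zero variance.
#' @export
structure_correlation <- function(netA, netB) {
  stopifnot(inherits(netA, "rf_network"), inherits(netB, "rf_network"))
  if (!identical(netA$labels, netB$labels))
    stop("networks must share the same node labels in the same order")
  a <- netA$weights[upper.tri(netA$weights)]
  b <- netB$weights[upper.tri(netB$weights)]
  if (sd(a) == 0 || sd(b) == 0) {
    warning("structure correlation undefined: zero edge-weight variance")
    return(NA_real_)
  }
  cor(a, b)
}

# EBIC for a glmnet path: gaussian uses n log(RSS/n), binomial the deviance
ebic_glmnet_pick <- function(fit, X, y, family, gamma) {
  n <- length(y)
  pth <- ncol(X)
  k <- fit$df
  if (family == "gaussian") {
    pred <- predict(fit, X)
    rss <- colSums((y - pred)^2)
    ebic <- n * log(rss / n) + k * log(n) + 2 * gamma * k * log(pth)
  } else {
    dev <- (1 - fit$dev.ratio) * fit$nulldev
    ebic <- dev + k * log(n) + 2 * gamma * k * log(pth)
  }
  which.min(ebic)
}

#' Nodewise predictability
#'
#' How well each node is explained by all other nodes, via nodewise
#' penalized regressions (penalty picked by EBIC with the same `gamma`
#' used for the network). Continuous nodes report `R^2 = 1 - SSE/SST`;
#' binary nodes report normalized accuracy
#' `(acc - acc0) / (1 - acc0)` beyond the modal class rate `acc0`,
#' floored at 0.
#'
#' @param table a single-group [study_table()] (rows with missing values
#'   are dropped per regression).
#' @param labels columns to evaluate (default: all non-item columns).
#' @param gamma EBIC hyperparameter.
#' @return Named numeric vector in `[0, 1]`.
#' @export
predictability <- function(table, labels = NULL, gamma = 0.5) {
  stopifnot(inherits(table, "rf_study_table"))
  if (is.null(labels))
    labels <- names(table$var_roles)[table$var_roles != "item"]
  X <- table$values[, labels, drop = FALSE]
  out <- stats::setNames(numeric(length(labels)), labels)
  for (v in labels) {
    others <- setdiff(labels, v)
    cc <- complete.cases(X[, c(v, others)])
    y <- X[cc, v]
    Z <- X[cc, others, drop = FALSE]
    single <- ncol(Z) < 2       # glmnet needs >= 2 predictors
    if (table$var_types[[v]] == "binary") {
      tab <- base::table(y)
      if (length(tab) < 2)
        stop("degenerate binary column '", v, "'")
      acc0 <- max(tab) / length(y)
      if (single) {
        pr <- stats::fitted(stats::glm(y ~ Z, family = stats::binomial()))
      } else {
        fit <- glmnet::glmnet(Z, y, family = "binomial")
        sel <- ebic_glmnet_pick(fit, Z, y, "binomial", gamma)
        pr <- predict(fit, Z, type = "response")[, sel]
      }
      acc <- mean((pr > 0.5) == y)
      out[v] <- max(0, (acc - acc0) / (1 - acc0))
    } else {
      if (single) {
        pred <- stats::fitted(stats::lm(y ~ Z))
      } else {
        fit <- glmnet::glmnet(Z, y, family = "gaussian")
        sel <- ebic_glmnet_pick(fit, Z, y, "gaussian", gamma)
        pred <- predict(fit, Z)[, sel]
      }
      r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
      out[v] <- min(1, max(0, r2))
    }
  }
  out
}

#' Centrality report for a network
#'
#' Bundles node strength, expected influence, optional predictability,
#' and the global statistics.
#'
#' @param net an [new_network()] object.
#' @param table optional matching single-group [study_table()] for
#'   predictability.
#' @param gamma EBIC hyperparameter for the predictability regressions.
#' @return Object of class `rf_centrality`: data.frame `nodes` plus
#'   `global_strength`, `global_expected_influence`.
#' @export
centrality_report <- function(net, table = NULL, gamma = 0.5) {
  stopifnot(inherits(net, "rf_network"))
  nodes <- data.frame(node = net$labels,
                      strength = node_strength(net),
                      expected_influence = expected_influence(net),
                      row.names = NULL)
  if (!is.null(table))
    nodes$predictability <-
      unname(predictability(table, net$labels, gamma)[net$labels])
  structure(list(nodes = nodes,
                 global_strength = global_strength(net),
                 global_expected_influence = global_expected_influence(net)),
            class = "rf_centrality")
}

#' @export
print.rf_centrality <- function(x, ...) {
  cat(sprintf("Global strength S = %.3f, global EI = %.3f\n",
              x$global_strength, x$global_expected_influence))
  print(x$nodes, digits = 3)
  invisible(x)
}

#' Shortest pathways to a target node
#'
#' Dijkstra's algorithm over edge distances `1 / |w_ij|` on the nonzero
#' edges (zero-weight pairs are non-adjacent, distance infinite). Ties
#' between equal-length routes are broken toward the lexicographically
#' smaller node sequence. A pathway is "direct" when the optimal route is
#' the single source-target edge.
#'
#' @param net an [new_network()] object.
#' @param sources source node labels (default: all nodes except the
#'   target).
#' @param target target node label.
#' @return Object of class `rf_paths`: data.frame with `source`,
#'   `length`, `direct`, and a `sequence` list-column of node paths
#'   (empty when unreachable, length `Inf`).
#' @export
shortest_pathways <- function(net, sources = NULL, target) {
  stopifnot(inherits(net, "rf_network"))
  if (!target %in% net$labels) stop("unknown target '", target, "'")
  if (is.null(sources)) sources <- setdiff(net$labels, target)
  if (!all(sources %in% net$labels)) stop("unknown source label")
  p <- length(net$labels)
  D <- 1 / abs(net$weights)          # Inf where no edge
  diag(D) <- Inf
  s <- match(target, net$labels)     # run once from the target (symmetric)
  dist <- rep(Inf, p); dist[s] <- 0
  paths <- vector("list", p); paths[[s]] <- s
  visited <- rep(FALSE, p)
  lex_order <- order(net$labels)
  lex_rank <- match(seq_len(p), lex_order)
  path_less <- function(a, b) {      # lexicographic compare on labels
    ra <- lex_rank[a]; rb <- lex_rank[b]
    n <- min(length(ra), length(rb))
    for (i in seq_len(n)) {
      if (ra[i] < rb[i]) return(TRUE)
      if (ra[i] > rb[i]) return(FALSE)
    }
    length(ra) < length(rb)
  }
  for (step in seq_len(p)) {
    cand <- which(!visited & is.finite(dist))
    if (!length(cand)) break
    u <- cand[order(dist[cand], lex_rank[cand])][1]
    visited[u] <- TRUE
    for (v in which(is.finite(D[u, ]) & !visited)) {
      alt <- dist[u] + D[u, v]
      newpath <- c(paths[[u]], v)
      if (alt < dist[v] ||
          (alt == dist[v] && path_less(newpath, paths[[v]]))) {
        dist[v] <- alt
        paths[[v]] <- newpath
      }
    }
  }
  idx <- match(sources, net$labels)
  seqs <- lapply(idx, function(i) {
    if (!is.finite(dist[i])) character(0)
    else net$labels[rev(paths[[i]])]   # target-rooted -> source-to-target
  })
  structure(list(
    table = data.frame(source = sources, length = dist[idx],
                       direct = vapply(seqs, length, 0L) == 2,
                       row.names = NULL),
    sequences = stats::setNames(seqs, sources),
    target = target), class = "rf_paths")
}

#' @export
print.rf_paths <- function(x, ...) {
  cat("Shortest pathways to '", x$target, "' (distance = 1/|w|):\n",
      sep = "")
  df <- x$table
  df$route <- vapply(x$sequences, paste, "", collapse = " -> ")
  print(df, digits = 3)
  invisible(x)
}
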