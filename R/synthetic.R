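#' Configuration of a synthetic two-group cohort
#'
#' Defines the complete ground truth of a simulated two-group study:
#' per-group sparse partial-correlation structures among the latent
#' variables, per-group mean shifts, binary thresholding rules, and an
#' optional ordinal item-measurement layer per continuous factor.
#'
#' Group reproducibility: group A always draws from `seed + 1` and group B
#' from `seed + 2`, so enlarging one group never perturbs the other.
#'
#' @param n_a,n_b persons per group (positive integers).
#' @param node_labels variable names.
#' @param node_types per-node `"continuous"` or `"binary"`.
#' @param true_partials_a,true_partials_b symmetric matrices of target
#'   partial correlations (zero diagonal, entries in (-1, 1)). The induced
#'   standardized precision `I - P` must be positive definite.
#' @param mean_shift matrix (2 x nodes, rows `a`, `b`) of latent mean
#'   offsets; defaults to zeros.
#' @param items_per_factor integer >= 0; 0 emits latent factor scores
#'   directly, otherwise each continuous node additionally emits that many
#'   ordinal indicator items.
#' @param loadings item loadings in (0, 1), recycled across items.
#' @param item_thresholds ordered latent cut points (standard-normal
#'   scale) shared by every item.
#' @param binary_thresholds named latent cut points for binary nodes; a
#'   person is coded 1 when their latent value exceeds the cut.
#' @param node_roles per-node role flag, defaults to
#'   `"resilience_factor"`.
#' @param missing_rate per-column missing-completely-at-random rate in
#'   \[0, 1); default 0.
#' @param seed master integer seed.
#'
#' @return An object of class `rf_generator_config`.
#' @export
generator_config <- function(n_a, n_b, node_labels, node_types,
                             true_partials_a, true_partials_b,
                             mean_shift = NULL,
                             items_per_factor = 0L,
                             loadings = 0.7,
                             item_thresholds = c(-0.8, 0.8),
                             binary_thresholds = NULL,
                             node_roles = NULL,
                             missing_rate = 0,
                             seed = 1L) {
  stopifnot(n_a >= 1, n_b >= 1, items_per_factor >= 0,
            missing_rate >= 0, missing_rate < 1)
  p <- length(node_labels)
  if (!all(node_types %in% c("continuous", "binary")))
    stop("node_types must be 'continuous' or 'binary'")
  check_partials <- function(P, nm) {
    P <- as.matrix(P)
    if (!isTRUE(all.equal(P, t(P), tolerance = 1e-10)))
      stop(nm, " must be symmetric")
    if (any(diag(P) != 0)) stop(nm, " must have a zero diagonal")
    if (any(abs(P[row(P) != col(P)]) >= 1))
      stop(nm, " entries must lie in (-1, 1)")
    ev <- eigen(diag(p) - P, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop(nm, ": induced precision is not positive definite ",
           "(smallest eigenvalue ", format(min(ev)), ")")
    P
  }
  true_partials_a <- check_partials(true_partials_a, "true_partials_a")
  true_partials_b <- check_partials(true_partials_b, "true_partials_b")
  if (is.null(mean_shift))
    mean_shift <- matrix(0, 2, p, dimnames = list(c("a", "b"), node_labels))
  if (any(diff(item_thresholds) <= 0))
    stop("item_thresholds must be strictly increasing")
  if (is.null(binary_thresholds))
    binary_thresholds <- stats::setNames(rep(0, sum(node_types == "binary")),
                                         node_labels[node_types == "binary"])
  if (is.null(node_roles)) node_roles <- rep("resilience_factor", p)
  loadings <- rep_len(loadings, max(1L, items_per_factor))
  if (any(loadings <= 0 | loadings >= 1))
    stop("loadings must lie in (0, 1)")
  structure(list(n_a = as.integer(n_a), n_b = as.integer(n_b),
                 node_labels = node_labels, node_types = node_types,
                 true_partials_a = true_partials_a,
                 true_partials_b = true_partials_b,
                 mean_shift = mean_shift,
                 items_per_factor = as.integer(items_per_factor),
                 loadings = loadings, item_thresholds = item_thresholds,
                 binary_thresholds = binary_thresholds,
                 node_roles = node_roles,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "rf_generator_config")
}

#' Correlation matrix implied by a partial-correlation matrix
#'
#' Inverts the partial-correlation construction of a Gaussian graphical
#' model: the standardized precision `K` with unit diagonal and
#' `K[i,j] = -partials[i,j]` is inverted and the result renormalized to
#' unit diagonal, so that the partial correlations of the returned matrix
#' equal the input exactly.
#'
#' @param partials symmetric matrix, zero diagonal, entries in (-1, 1).
#' @return Positive-definite correlation matrix with unit diagonal.
#' @export
#' @examples
#' P <- matrix(0, 3, 3); P[1, 2] <- P[2, 1] <- P[2, 3] <- P[3, 2] <- 0.4
#' S <- build_covariance_from_partials(P)
build_covariance_from_partials <- function(partials) {
  partials <- as.matrix(partials)
  p <- nrow(partials)
  if (!isTRUE(all.equal(partials, t(partials), tolerance = 1e-10)))
    stop("partials must be symmetric")
  if (any(diag(partials) != 0)) stop("partials must have zero diagonal")
  if (any(abs(partials[row(partials) != col(partials)]) >= 1))
    stop("partial correlations must lie in (-1, 1)")
  K <- diag(p) - partials
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("induced precision is not positive definite (smallest eigenvalue ",
         format(min(ev)), ")")
  S <- stats::cov2cor(solve(K))
  dimnames(S) <- dimnames(partials)
  (S + t(S)) / 2
}

group_seed <- function(config, which) {
  config$seed + match(which, c("a", "b"))
}

#' Generate one group's data block
#'
#' Draws latent multivariate normal scores under the group's true network
#' and mean shifts, thresholds binary nodes, and (optionally) emits
#' ordinal indicator items `y = loading * factor + sqrt(1 - loading^2) *
#' noise` cut at the configured thresholds. Deterministic given the config
#' seed and group id.
#'
#' @param config an [generator_config()] object.
#' @param which `"a"` or `"b"`.
#' @return A single-group [study_table()].
#' @export
generate_group <- function(config, which = c("a", "b")) {
  stopifnot(inherits(config, "rf_generator_config"))
  which <- match.arg(which)
  n <- if (which == "a") config$n_a else config$n_b
  P <- if (which == "a") config$true_partials_a else config$true_partials_b
  p <- length(config$node_labels)
  S <- build_covariance_from_partials(P)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(group_seed(config, which))
  Z <- matrix(stats::rnorm(n * p), n, p) %*% chol(S)
  Z <- sweep(Z, 2, config$mean_shift[which, ], "+")
  colnames(Z) <- config$node_labels
  vals <- Z
  types <- ifelse(config$node_types == "binary", "binary", "continuous")
  roles <- config$node_roles
  for (j in which(config$node_types == "binary")) {
    cut <- config$binary_thresholds[[config$node_labels[j]]]
    vals[, j] <- as.numeric(Z[, j] > cut)
  }
  if (config$items_per_factor > 0) {
    for (j in which(config$node_types == "continuous")) {
      for (m in seq_len(config$items_per_factor)) {
        lam <- config$loadings[m]
        y <- lam * Z[, j] + sqrt(1 - lam^2) * stats::rnorm(n)
        item <- findInterval(y, config$item_thresholds)
        col <- matrix(as.numeric(item), n, 1)
        colnames(col) <- paste0(config$node_labels[j], "_item", m)
        vals <- cbind(vals, col)
        types <- c(types, "ordinal")
        roles <- c(roles, "item")
      }
    }
  }
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(length(vals)) < config$missing_rate,
                   nrow(vals))
    vals[miss] <- NA_real_
  }
  study_table(vals, rep(which, n), types, roles)
}

#' Generate a complete two-group synthetic study
#'
#' Concatenates the two independently seeded group blocks of
#' [generate_group()] with group labels `"a"` and `"b"`.
#'
#' @param config an [generator_config()] object.
#' @return A two-group [study_table()].
#' @export
generate_two_group_study <- function(config) {
  a <- generate_group(config, "a")
  b <- generate_group(config, "b")
  study_table(rbind(a$values, b$values),
              c(as.character(a$group), as.character(b$group)),
              a$var_types, a$var_roles)
}

# save/restore of .Random.seed so generators do not disturb the caller's
# random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Default study-like synthetic cohort configuration
#'
#' A ready-made two-group configuration mirroring the structure of an
#' adversity-exposed vs non-exposed adolescent cohort: 10 resilience
#' factors (8 continuous, 2 binary) plus one continuous general-distress
#' node, group sizes 638 and 501. Group B (the non-exposed analogue) has
#' sparse all-positive factor-factor partial correlations and weaker
#' factor-distress edges; group A mixes in a minority of negative
#' factor-factor partials, stronger factor-distress edges, lower factor
#' means and a higher distress mean. Shapes only: the true edge values are
#' this package's own choices, not estimates from any cohort.
#'
#' @param seed master seed.
#' @param items_per_factor ordinal indicator items per continuous node
#'   (0 = emit factor scores directly).
#' @param missing_rate per-column MCAR rate.
#' @return An [generator_config()] object.
#' @export
paper_like_config <- function(seed = 1L, items_per_factor = 0L,
                              missing_rate = 0) {
  labels <- c("friend_support", "family_support", "family_cohesion",
              "negative_self_esteem", "positive_self_esteem", "brooding",
              "reflection", "distress_tolerance", "aggression",
              "expressive_suppression", "general_distress")
  types <- c(rep("continuous", 8), "binary", "binary", "continuous")
  roles <- c(rep("resilience_factor", 10), "distress")
  p <- 11
  edge <- function(P, i, j, w) { P[i, j] <- P[j, i] <- w; P }
  # group B: sparse, all-positive RF-RF couplings; mild RF-distress edges
  Pb <- matrix(0, p, p, dimnames = list(labels, labels))
  Pb <- edge(Pb, 1, 2, 0.22)   # friend - family support
  Pb <- edge(Pb, 2, 3, 0.30)   # family support - cohesion
  Pb <- edge(Pb, 4, 5, 0.28)   # negative - positive self-esteem
  Pb <- edge(Pb, 4, 6, 0.22)   # negative self-esteem - brooding
  Pb <- edge(Pb, 6, 7, 0.30)   # brooding - reflection
  Pb <- edge(Pb, 5, 8, 0.18)   # positive self-esteem - distress tolerance
  Pb <- edge(Pb, 1, 10, 0.15)  # friend support - expressive suppression
  Pb <- edge(Pb, 3, 9, 0.15)   # family cohesion - aggression
  Pb <- edge(Pb, 4, 11, -0.25) # negative self-esteem - distress
  Pb <- edge(Pb, 6, 11, -0.20) # brooding - distress
  Pb <- edge(Pb, 5, 11, -0.12)
  # group A: same backbone, a minority of negative RF-RF partials and
  # stronger, more numerous RF-distress edges
  Pa <- Pb
  Pa <- edge(Pa, 1, 10, -0.15) # suppression-friendship flips sign
  Pa <- edge(Pa, 7, 8, -0.12)
  Pa <- edge(Pa, 4, 11, -0.35)
  Pa <- edge(Pa, 6, 11, -0.30)
  Pa <- edge(Pa, 9, 11, -0.20)
  Pa <- edge(Pa, 1, 11, -0.15)
  Pa <- edge(Pa, 5, 11, -0.18)
  shift <- matrix(0, 2, p, dimnames = list(c("a", "b"), labels))
  shift["a", ] <- c(rep(-0.12, 8), -0.2, -0.2, 0.3)
  shift["b", ] <- c(rep(0.12, 8), 0.2, 0.2, -0.16)
  generator_config(n_a = 638, n_b = 501, node_labels = labels,
                   node_types = types, true_partials_a = Pa,
                   true_partials_b = Pb, mean_shift = shift,
                   items_per_factor = items_per_factor,
                   loadings = c(0.8, 0.7, 0.65, 0.6, 0.55),
                   item_thresholds = c(-1.1, -0.2, 0.8),
                   binary_thresholds = c(aggression = 0.8,
                                         expressive_suppression = 0.35),
                   node_roles = roles, missing_rate = missing_rate,
                   seed = seed)
}

#' Read / write a generator configuration as JSON
#'
#' @param config an [generator_config()] object.
#' @param path file path.
#' @return `write_generator_config` returns `path` invisibly;
#'   `read_generator_config` the reconstructed config.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "rf_generator_config"))
  x <- unclass(config)
  x$binary_thresholds <- as.list(x$binary_thresholds)  # keep names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(x$node_labels)
  mk <- function(m, nr, dn) {
    if (!is.matrix(m)) m <- matrix(unlist(m), nr, byrow = TRUE)
    dimnames(m) <- dn
    m
  }
  dn <- list(x$node_labels, x$node_labels)
  generator_config(x$n_a, x$n_b, x$node_labels, x$node_types,
                   mk(x$true_partials_a, p, dn),
                   mk(x$true_partials_b, p, dn),
                   mk(x$mean_shift, 2, list(c("a", "b"), x$node_labels)),
                   x$items_per_factor, x$loadings, x$item_thresholds,
                   unlist(x$binary_thresholds), x$node_roles,
                   x$missing_rate, x$seed)
}
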