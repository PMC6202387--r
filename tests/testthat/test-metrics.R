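test_that("strength and expected influence follow their definitions", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.3
  W[1, 3] <- W[3, 1] <- -0.2
  net <- new_network(W, c("a", "b", "c"))
  expect_equal(unname(node_strength(net)), c(0.5, 0.3, 0.2))
  expect_equal(unname(expected_influence(net)), c(0.1, 0.3, -0.2))
  expect_equal(global_strength(net), 0.5)
  expect_equal(global_expected_influence(net), 0.1)
  empty <- new_network(matrix(0, 4, 4))
  expect_equal(unname(node_strength(empty)), rep(0, 4))
  expect_equal(global_strength(empty), 0)
})

test_that("centrality identities hold on randomized networks", {
  for (seed in 1:25) {
    net <- rand_net(6, density = 0.5, seed = seed)
    s <- node_strength(net)
    e <- expected_influence(net)
    expect_true(all(s >= abs(e) - 1e-12))
    expect_equal(global_strength(net), sum(s) / 2, tolerance = 1e-12)
    expect_equal(global_expected_influence(net), sum(e) / 2,
                 tolerance = 1e-12)
    expect_gte(global_strength(net), abs(global_expected_influence(net)))
    neg <- new_network(-net$weights, net$labels)
    expect_equal(expected_influence(neg), -e)
    expect_equal(node_strength(neg), s)
    # all-positive network: strength equals EI
    pos <- new_network(abs(net$weights), net$labels)
    expect_equal(node_strength(pos), expected_influence(pos))
  }
})

test_that("structure correlation matches the direct formula", {
  net <- rand_net(6, seed = 31)
  expect_equal(structure_correlation(net, net), 1)
  neg <- new_network(-net$weights, net$labels)
  expect_equal(structure_correlation(net, neg), -1)
  other <- rand_net(6, seed = 32)
  other$labels <- net$labels
  dimnames(other$weights) <- dimnames(net$weights)
  up <- upper.tri(net$weights)
  a <- net$weights[up]; b <- other$weights[up]
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(structure_correlation(net, other), direct,
               tolerance = 1e-12)
  empty <- new_network(matrix(0, 6, 6), net$labels)
  expect_warning(r <- structure_correlation(net, empty), "undefined")
  expect_true(is.na(r))
})

test_that("predictability estimates variance explained and normalized accuracy", {
  set.seed(301)
  n <- 2000
  # pure noise: near-zero predictability
  Xn <- matrix(rnorm(n * 4), n, 4,
               dimnames = list(NULL, paste0("v", 1:4)))
  noise_tab <- study_table(Xn, rep("g", n))
  expect_true(all(predictability(noise_tab) <= 0.05))
  # y = 0.8 x + e, Var(e) = 0.36 -> R^2 = 0.64
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n, sd = 0.6)
  tab <- study_table(cbind(x = x, y = y, z = rnorm(n)), rep("g", n))
  pr <- predictability(tab)
  expect_lt(abs(pr[["y"]] - 0.64), 0.05)
  # binary node driven by a continuous one has positive normalized accuracy
  b <- as.numeric(x + rnorm(n, sd = 0.5) > 0)
  tab2 <- study_table(cbind(x = x, b = b), rep("g", n),
                      c("continuous", "binary"))
  pr2 <- predictability(tab2)
  expect_gt(pr2[["b"]], 0.3)
  # binary node unrelated to the predictors: floored at ~0
  b0 <- rbinom(n, 1, 0.3)
  tab3 <- study_table(cbind(x = x, z = rnorm(n), b0 = b0), rep("g", n),
                      c("continuous", "continuous", "binary"))
  expect_lte(predictability(tab3)[["b0"]], 0.05)
})

test_that("two-node and three-node pathway arithmetic is exact", {
  W <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  W[1, 2] <- W[2, 1] <- 0.5
  pr <- shortest_pathways(new_network(W), target = "b")
  expect_equal(pr$table$length, 2)
  expect_true(pr$table$direct)
  expect_equal(pr$sequences[["a"]], c("a", "b"))
  # direct edge 0.5 (d = 2) beats the 0.9/0.9 two-hop (d ~ 2.22)
  W3 <- matrix(0, 3, 3, dimnames = list(c("s", "m", "t"), c("s", "m", "t")))
  W3[1, 3] <- W3[3, 1] <- 0.5
  W3[1, 2] <- W3[2, 1] <- 0.9
  W3[2, 3] <- W3[3, 2] <- 0.9
  pr3 <- shortest_pathways(new_network(W3), sources = "s", target = "t")
  expect_true(pr3$table$direct)
  expect_equal(pr3$table$length, 2)
  # weaken the direct edge and the indirect route wins
  W3[1, 3] <- W3[3, 1] <- 0.4
  pr4 <- shortest_pathways(new_network(W3), sources = "s", target = "t")
  expect_false(pr4$table$direct)
  expect_equal(pr4$sequences[["s"]], c("s", "m", "t"))
  expect_equal(pr4$table$length, 1 / 0.9 + 1 / 0.9)
})

test_that("Dijkstra agrees with Floyd-Warshall on 200 random networks", {
  for (seed in 1:200) {
    net <- rand_net(8, density = 0.3, seed = 400 + seed)
    fw <- floyd_warshall(net)
    target <- net$labels[1 + (seed %% 8)]
    pr <- shortest_pathways(net, target = target)
    expect_equal(pr$table$length,
                 unname(fw[setdiff(net$labels, target), target]))
    # reported length equals the sum of inverse absolute weights en route
    for (src in pr$table$source) {
      sq <- pr$sequences[[src]]
      if (length(sq) < 2) {
        expect_equal(pr$table$length[pr$table$source == src], Inf)
      } else {
        d <- sum(vapply(seq_len(length(sq) - 1), function(i)
          1 / abs(net$weights[sq[i], sq[i + 1]]), 0))
        expect_equal(pr$table$length[pr$table$source == src], d)
      }
    }
  }
})

test_that("stronger factor-distress edges create more direct pathways", {
  # same factor-factor backbone; scale the distress column up in net2
  base <- matrix(0, 5, 5,
                 dimnames = rep(list(c(paste0("r", 1:4), "gd")), 2))
  base[1, 2] <- base[2, 1] <- 0.45
  base[2, 3] <- base[3, 2] <- 0.45
  base[3, 4] <- base[4, 3] <- 0.45
  weak <- strong <- base
  weak[1, 5] <- weak[5, 1] <- 0.3    # only r1 touches distress
  strong[, 5] <- strong[5, ] <- c(0.3, 0.3, 0.3, 0.3, 0)
  n_direct <- function(W)
    sum(shortest_pathways(new_network(W), target = "gd")$table$direct)
  expect_gt(n_direct(strong), n_direct(weak))
  expect_equal(n_direct(strong), 4)
})

test_that("centrality reports bundle node and global statistics", {
  net <- rand_net(5, seed = 51)
  rep_ <- centrality_report(net)
  expect_equal(rep_$nodes$strength, unname(node_strength(net)))
  expect_equal(rep_$global_strength, global_strength(net))
  expect_equal(rep_$global_expected_influence,
               global_expected_influence(net))
})
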