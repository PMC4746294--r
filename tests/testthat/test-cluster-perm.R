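test_that("adjacency is symmetric, irreflexive, and distance-driven", {
  # two distant channels -> no neighbours (absolute cap: the quantile of a
  # single pairwise distance is degenerate)
  far <- data.frame(label = c("a", "b"), x = c(0, 10), y = 0)
  adj_far <- build_adjacency(far, 0.1, max_distance = 1)
  expect_true(all(lengths(adj_far$neighbors) == 0))
  # tight cluster -> complete graph
  adj_tight <- build_adjacency(tight_layout(4), 1)
  expect_true(all(lengths(adj_tight$neighbors) == 3))
  # random layouts: symmetric, irreflexive
  set.seed(71)
  lay <- data.frame(label = paste0("c", 1:12), x = runif(12), y = runif(12))
  adj <- build_adjacency(lay, 0.3)
  expect_true(isSymmetric(adj$matrix))
  expect_true(all(!diag(adj$matrix)))
})

test_that("channel t-maps equal the hand t formulas", {
  set.seed(72)
  a <- matrix(rnorm(7 * 3), 7, 3)
  expect_true(all(channel_tmap(a, a, paired = TRUE) == 0))
  expect_true(all(abs(channel_tmap(a, a)) < 1e-12))
  b <- matrix(rnorm(5 * 3, 1), 5, 3)
  t1 <- channel_tmap(a, b)[1]
  # pooled-variance Student t by hand
  x <- a[, 1]; y <- b[, 1]
  sp2 <- (6 * var(x) + 4 * var(y)) / 10
  expect_equal(unname(t1), (mean(x) - mean(y)) / sqrt(sp2 * (1 / 7 + 1 / 5)),
               tolerance = 1e-12)
  expect_equal(attr(channel_tmap(a, b), "df"), 10)
  d <- a - a[7:1, ]
  tp <- channel_tmap(a, a[7:1, ], paired = TRUE)[2]
  expect_equal(unname(tp), mean(d[, 2]) / (sd(d[, 2]) / sqrt(7)),
               tolerance = 1e-12)
})

test_that("cluster formation honours adjacency, sign, and minimum extent", {
  lay <- grid_layout(1, 6)   # a chain: ch1 - ch2 - ... - ch6
  adj <- build_adjacency(lay, 0.3)
  tmap <- c(5, 0, 0, 5, 5, 0)
  attr(tmap, "df") <- 12
  cl <- find_clusters(tmap, adj)
  # the isolated supra-threshold channel is discarded (min extent 2)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$channels, "ch04,ch05")
  expect_equal(cl$mass, 10)
  expect_equal(cl$mean_t, 5)
  # opposite signs never join
  tmap2 <- c(5, -5, 0, 0, 0, 0)
  attr(tmap2, "df") <- 12
  expect_equal(nrow(find_clusters(tmap2, adj)), 0)
  tmap3 <- c(-5, -5, 0, 0, 0, 0)
  attr(tmap3, "df") <- 12
  cl3 <- find_clusters(tmap3, adj)
  expect_equal(cl3$mean_t, -5)   # negative clusters keep signed mean t
  expect_equal(cl3$mass, 10)     # mass uses |t|
})

test_that("connected components match an independent graph-search oracle", {
  skip_if_not_installed("igraph")
  set.seed(73)
  lay <- grid_layout(4, 5)
  adj <- build_adjacency(lay, 0.12)
  for (i in 1:20) {
    tmap <- ifelse(runif(20) < 0.4, 5, 0)
    attr(tmap, "df") <- 10
    cl <- find_clusters(tmap, adj, min_extent = 1)
    # oracle: components of the subgraph induced by supra channels
    g <- igraph::graph_from_adjacency_matrix(
      adj$matrix[tmap > 0, tmap > 0, drop = FALSE], mode = "undirected")
    comp <- igraph::components(g)
    sizes <- sort(as.integer(table(comp$membership)))
    expect_equal(sort(cl$n_channels), sizes)
  }
})

test_that("permutation p equals the exhaustive-enumeration oracle for 3 vs 3", {
  set.seed(74)
  lay <- tight_layout(4)
  adj <- build_adjacency(lay, 1)
  a <- matrix(rnorm(12, 1.5), 3, 4)
  b <- matrix(rnorm(12), 3, 4)
  res <- permutation_test(a, b, adj, n_perm = 500, seed = 75)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, choose(6, 3))
  # independent oracle: enumerate all C(6,3) relabellings by hand
  X <- rbind(a, b)
  combs <- combn(6, 3)
  max_mass <- apply(combs, 2, function(idx) {
    t <- channel_tmap(X[idx, , drop = FALSE], X[-idx, , drop = FALSE])
    cl <- find_clusters(t, adj)
    if (nrow(cl) == 0) 0 else max(cl$mass)
  })
  for (i in seq_len(nrow(res$clusters))) {
    oracle_p <- mean(max_mass >= res$clusters$mass[i])
    expect_equal(res$clusters$p[i], oracle_p, tolerance = 1e-12)
  }
})

test_that("a massive localised effect reaches the smallest attainable p", {
  set.seed(76)
  lay <- grid_layout(2, 4)
  adj <- build_adjacency(lay, 0.2)
  a <- matrix(rnorm(7 * 8, 0, 0.1), 7, 8)
  b <- a
  b[, 1:2] <- b[, 1:2] + 10   # overwhelming 2-channel effect
  res <- permutation_test(a, b, adj, n_perm = 500, seed = 77)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$n_channels, 2)
  expect_equal(res$clusters$p, 1 / 500)
  expect_true(res$clusters$significant)
  # reported mean t is the average of member-channel t values
  tmap <- channel_tmap(a, b)
  expect_equal(res$clusters$mean_t, mean(tmap[1:2]), tolerance = 1e-12)
})

test_that("cluster p is monotone in effect amplitude on a fixed noise draw", {
  set.seed(78)
  lay <- grid_layout(3, 4)
  adj <- build_adjacency(lay, 0.15)
  base_a <- matrix(rnorm(8 * 12), 8, 12)
  base_b <- matrix(rnorm(8 * 12), 8, 12)
  p_at <- function(amp) {
    b <- base_b; b[, 1:3] <- b[, 1:3] + amp
    res <- permutation_test(base_a, b, adj, n_perm = 200, seed = 79)
    if (nrow(res$clusters) == 0) 1 else min(res$clusters$p)
  }
  ps <- vapply(c(0.5, 1.5, 3, 6), p_at, 0)
  expect_true(all(diff(ps) <= 0))
})

test_that("permutation results are reproducible under a fixed seed", {
  set.seed(80)
  a <- matrix(rnorm(7 * 10), 7, 10)
  b <- matrix(rnorm(7 * 10, 0.5), 7, 10)
  adj <- build_adjacency(grid_layout(2, 5), 0.2)
  r1 <- permutation_test(a, b, adj, n_perm = 300, seed = 81)
  r2 <- permutation_test(a, b, adj, n_perm = 300, seed = 81)
  expect_identical(r1$clusters, r2$clusters)
  expect_identical(r1$null_max, r2$null_max)
})

test_that("paired sign-flip permutations enumerate exhaustively for small n", {
  set.seed(82)
  a <- matrix(rnorm(3 * 4, 2), 3, 4)
  b <- matrix(rnorm(3 * 4), 3, 4)
  adj <- build_adjacency(tight_layout(4), 1)
  res <- permutation_test(a, b, adj, paired = TRUE, n_perm = 500)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 2^3)
  expect_true(all(res$clusters$p >= 1 / 8))
})
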