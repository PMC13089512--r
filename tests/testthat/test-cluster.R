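test_that("pearson_r matches the textbook formula and rejects bad input", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  y <- c(2, 1, 4, 3, 6)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), oracle)
  expect_error(pearson_r(x, rep(1, 5)), "constant")
  expect_error(pearson_r(1:2, 2:1), "three")
})

test_that("channel adjacency is symmetric, irreflexive, with median degree ~6", {
  adj <- channel_adjacency(montage_1020())
  expect_true(isSymmetric(adj$adj))
  expect_true(all(diag(adj$adj) == FALSE))
  expect_gte(median(rowSums(adj$adj)), 6)
  expect_equal(length(adj$isolated), 0)
  # reduced montages may flag isolated channels rather than fail
  tiny <- channel_adjacency(montage_1020(c("Fpz", "Oz")), target_degree = 1)
  expect_true(all(rowSums(tiny$adj) >= 1))
})

test_that("topography sign-flip test finds planted effects and respects nulls", {
  adj <- channel_adjacency(montage_1020())
  n_ch <- length(adj$channels)
  set.seed(11)

  # all-identical zero maps: no suprathreshold points at all
  zero <- matrix(0, 8, n_ch)
  res0 <- topo_cluster_test(zero, adj, n_perm = 200, seed = 1)
  expect_equal(nrow(res0$clusters), 0)
  expect_true(all(is.na(res0$statistic$t)))

  # uniform +2 dB effect: a single whole-scalp positive cluster
  x <- matrix(2 + rnorm(17 * n_ch, 0, 0.5), 17, n_ch)
  res <- topo_cluster_test(x, adj, n_perm = 500, seed = 2)
  top <- res$clusters[1, ]
  expect_true(top$significant && top$sign == 1)
  expect_equal(top$n_members, n_ch)

  # posterior-only effect: detected cluster within posterior set + neighbours
  set.seed(11)
  post <- posterior_channels(montage_1020())
  eff <- ifelse(adj$channels %in% post, 2, 0)
  xp <- matrix(rnorm(17 * n_ch, 0, 0.6), 17, n_ch) +
    matrix(eff, 17, n_ch, byrow = TRUE)
  resp <- topo_cluster_test(xp, adj, n_perm = 500, seed = 3)
  sig <- resp$clusters[resp$clusters$significant & resp$clusters$sign > 0, ]
  expect_gte(nrow(sig), 1)
  neighbours <- adj$channels[colSums(adj$adj[adj$channels %in% post, ]) > 0]
  allowed <- union(post, neighbours)
  expect_true(all(unlist(sig$members) %in% allowed))
})

test_that("Monte Carlo p-values obey the add-one floor and are seed-stable", {
  adj <- channel_adjacency(montage_1020())
  set.seed(4)
  x <- matrix(3 + rnorm(12 * length(adj$channels), 0, 0.3), 12)
  res <- topo_cluster_test(x, adj, n_perm = 100, seed = 7)
  expect_gte(min(res$clusters$p), 1 / 101)
  res2 <- topo_cluster_test(x, adj, n_perm = 100, seed = 7)
  expect_identical(res$clusters$p, res2$clusters$p)
  # permutation distributions converge: two long runs give close p
  ra <- topo_cluster_test(x, adj, n_perm = 1500, seed = 8)
  rb <- topo_cluster_test(x, adj, n_perm = 1500, seed = 9)
  expect_lt(abs(ra$clusters$p[1] - rb$clusters$p[1]),
            3 * sqrt(0.05 * 0.95 / 1500) + 1e-6)
})

test_that("cluster membership is invariant under channel reordering", {
  m <- montage_1020()
  adj <- channel_adjacency(m)
  set.seed(5)
  post <- posterior_channels(m)
  eff <- ifelse(m$channel %in% post, 1.5, 0)
  x <- matrix(rnorm(15 * nrow(m), 0, 0.5), 15) +
    matrix(eff, 15, nrow(m), byrow = TRUE)
  colnames(x) <- m$channel
  res1 <- topo_cluster_test(x, adj, n_perm = 300, seed = 11)

  perm <- sample(nrow(m))
  m2 <- m[perm, ]
  adj2 <- channel_adjacency(m2)
  res2 <- topo_cluster_test(x[, m2$channel], adj2, n_perm = 300, seed = 11)
  sets1 <- lapply(res1$clusters$members, sort)
  sets2 <- lapply(res2$clusters$members, sort)
  expect_setequal(sets1, sets2)
})

test_that("time-frequency clustering recovers a planted burst region", {
  freqs <- seq(5, 40, 1)
  times <- seq(-3, 14, 0.1)
  n_sub <- 17
  set.seed(21)
  x <- array(rnorm(n_sub * length(freqs) * length(times), 0, 1),
             dim = c(n_sub, length(freqs), length(times)))
  f_in <- freqs >= 8 & freqs <= 11.8
  t_in <- times >= 0 & times <= 6
  x[, f_in, t_in] <- x[, f_in, t_in] + 1.5
  res <- tf_cluster_test(x, freqs, times, n_perm = 300, seed = 5)
  sig <- res$clusters[res$clusters$significant & res$clusters$sign > 0, ]
  expect_gte(nrow(sig), 1)
  mem <- sig$members[[1]]
  planted <- sum(mem$freq >= 8 & mem$freq <= 11.8 & mem$time >= 0 & mem$time <= 6)
  expect_gte(planted / sum(f_in) / sum(t_in), 0.8)  # covers >= 80% of the region

  # all-identical maps: empty result
  x0 <- array(0, dim = c(5, 5, 30))
  res0 <- tf_cluster_test(x0, 1:5 + 5, seq(-2.5, 0.4, 0.1), n_perm = 50,
                          baseline = c(-2, -1), post = c(0, 0.4), seed = 1)
  expect_equal(nrow(res0$clusters), 0)
})

test_that("correlation clustering is exact for perfect coupling and errors on constants", {
  m <- montage_1020()
  adj <- channel_adjacency(m)
  set.seed(6)
  x <- matrix(rnorm(17 * nrow(m)), 17)
  colnames(x) <- m$channel
  oz <- match("Oz", m$channel)
  behavior <- 2 * x[, oz] + 1    # exact linear function of one channel
  res <- topo_cluster_correlation(x, behavior, adj, n_perm = 300, seed = 3)
  expect_equal(res$statistic$r[oz], 1)
  sig <- res$clusters[res$clusters$significant, ]
  expect_true(any(vapply(sig$members, function(mm) "Oz" %in% mm, logical(1))))

  expect_error(topo_cluster_correlation(x, rep(1, 17), adj), "constant")
  expect_error(topo_cluster_correlation(x[1:3, ], behavior[1:3], adj), "four")
})
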