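test_that("intra-cluster link counting matches direct enumeration", {
  g <- clique_graph(c(4, 4))
  nodes <- igraph::V(g$graph)$name
  one <- setNames(rep(1, 8), nodes)
  expect_equal(intra_cluster_links(g, one), igraph::ecount(g$graph))
  singletons <- setNames(seq_len(8), nodes)
  expect_equal(intra_cluster_links(g, singletons), 0L)
  # 4-cycle split into two adjacent pairs keeps exactly 2 edges internal
  cyc <- cell_graph(data.frame(from = c("a", "b", "c", "d"),
                               to = c("b", "c", "d", "a"), weight = 1),
                    nodes = c("a", "b", "c", "d"), stage = "final")
  expect_equal(intra_cluster_links(cyc, c(a = 1, b = 1, c = 2, d = 2)), 2L)
  expect_error(intra_cluster_links(cyc, c(a = 1, b = 1, c = 2)), "missing")
})

test_that("refining a partition never increases the intra-cluster link count", {
  set.seed(71)
  for (rep in 1:10) {
    edges <- random_graph_edges(12, 0.4)
    g <- cell_graph(data.frame(from = edges[, 1], to = edges[, 2], weight = 1),
                    nodes = sprintf("c%02d", 1:12), stage = "final")
    part <- setNames(sample(3, 12, replace = TRUE), sprintf("c%02d", 1:12))
    finer <- part + sample(0:1, 12, replace = TRUE) * 3 # split some blocks
    expect_lte(intra_cluster_links(g, finer), intra_cluster_links(g, part))
  }
})

test_that("resolution scan is deterministic and respects cluster structure", {
  g <- clique_graph(c(6, 6), bridges = cbind("c01", "c07"))
  s1 <- scan_resolutions(g, gammas = seq(0.1, 2, by = 0.1), seed = 5)
  s2 <- scan_resolutions(g, gammas = seq(0.1, 2, by = 0.1), seed = 5)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$memberships, s2$memberships)
  m <- igraph::ecount(g$graph)
  # at the lowest resolution: one cluster (kin = m) or the two cliques
  # (kin = m - 1, only the bridge crossing)
  expect_true(s1$table$kin[1] %in% c(m, m - 1L))
  expect_true(all(s1$table$kin <= m))
  expect_error(scan_resolutions(g, gammas = c(0.5, 1)), "5")
})

test_that("an all-singleton solution carries zero intra-cluster links", {
  g <- clique_graph(c(3, 3))
  nodes <- igraph::V(g$graph)$name
  expect_equal(intra_cluster_links(g, setNames(seq_along(nodes), nodes)), 0L)
})

test_that("first breakpoint matches exhaustive single-split search on clean steps", {
  sc <- fake_scan(seq(0.1, 0.6, by = 0.1), c(10, 10, 10, 6, 6, 2))
  bp <- detect_first_breakpoint(sc)
  expect_gt(bp$gamma_prime, 0.3)
  expect_lte(bp$gamma_prime, 0.4)
  expect_equal(bp$regime_idx, 1:3)
  expect_equal(bp$gamma_prime,
               best_single_split(sc$table$gamma, sc$table$kin))

  sc2 <- fake_scan(seq(0.1, 0.5, by = 0.1), c(10, 10, 10, 2, 2))
  bp2 <- detect_first_breakpoint(sc2)
  expect_equal(bp2$gamma_prime,
               best_single_split(sc2$table$gamma, sc2$table$kin))
  expect_equal(bp2$regime_idx, 1:3)

  # clean two-regime profiles: the breakpoint is the exhaustive SSE minimiser
  set.seed(81)
  for (rep in 1:6) {
    lens <- sample(3:12, 2, replace = TRUE)
    kin <- rep(c(100, 100 - sample(30:80, 1)), times = lens)
    gam <- seq_along(kin) * 0.05
    bp3 <- detect_first_breakpoint(fake_scan(gam, kin))
    expect_equal(bp3$gamma_prime, best_single_split(gam, kin))
    expect_equal(bp3$regime_idx, seq_len(lens[1]))
  }

  # three-regime profiles: the first regime ends at the first constructed step
  set.seed(82)
  for (rep in 1:6) {
    lens <- sample(3:8, 3, replace = TRUE)
    kin <- rep(c(100, 100 - sample(40:60, 1), 10), times = lens)
    gam <- seq_along(kin) * 0.05
    bp4 <- detect_first_breakpoint(fake_scan(gam, kin))
    expect_equal(bp4$regime_idx, seq_len(lens[1]))
    expect_equal(bp4$gamma_prime, (gam[lens[1]] + gam[lens[1] + 1]) / 2)
  }
})

test_that("a one-point transient at the grid edge is not a stable regime", {
  # K_in settles on its plateau only from the second grid point on; the
  # stable regime must skip the transient instead of averaging it in
  kin <- c(900, rep(754, 12), rep(600, 7))
  gam <- seq(0.05, by = 0.05, length.out = length(kin))
  bp <- detect_first_breakpoint(fake_scan(gam, kin))
  expect_equal(bp$regime_idx, 2:13)
  expect_gt(bp$gamma_prime, gam[13] - 1e-9)
  expect_lte(bp$gamma_prime, gam[14])
})

test_that("constant profiles yield no breakpoint; detection is affine-invariant", {
  sc <- fake_scan(seq(0.1, 0.8, by = 0.1), rep(42, 8))
  bp <- detect_first_breakpoint(sc)
  expect_equal(bp$regime_idx, 1:8)
  expect_equal(bp$gamma_prime, 0.8)
  expect_length(bp$split_points, 0)

  base <- c(20, 20, 20, 20, 8, 8, 8, 3, 3, 3)
  gam <- seq(0.1, 1, by = 0.1)
  b1 <- detect_first_breakpoint(fake_scan(gam, base))
  b2 <- detect_first_breakpoint(fake_scan(gam, 2.5 * base + 7))
  b3 <- detect_first_breakpoint(fake_scan(gam, -1.5 * base - 2))
  expect_equal(b1$gamma_prime, b2$gamma_prime)
  expect_equal(b1$regime_idx, b2$regime_idx)
  expect_equal(b1$gamma_prime, b3$gamma_prime)
})

test_that("adapt_split picks the lower-median resolution of the first regime", {
  # two clean cliques: every resolution yields the same two-clique solution,
  # so whatever the regime, the partition must be the cliques
  g <- clique_graph(c(8, 8), bridges = cbind("c01", "c09"))
  out <- adapt_split(g, gammas = seq(0.1, 2, by = 0.1), seed = 9)
  part <- out$partition
  expect_equal(length(unique(part)), 2)
  expect_equal(length(unique(part[sprintf("c%02d", 1:8)])), 1)
  expect_equal(length(unique(part[sprintf("c%02d", 9:16)])), 1)
  expect_false(out$no_split)
  # gamma_f is a grid point inside the first regime at its lower median
  scan <- out$scan
  bp <- detect_first_breakpoint(scan)
  idx <- bp$regime_idx
  expect_equal(out$gamma_f, scan$table$gamma[idx[floor((length(idx) + 1) / 2)]])
})

test_that("disconnected cliques are recovered exactly for any grid", {
  g <- clique_graph(c(7, 9))
  out <- adapt_split(g, gammas = seq(0.2, 2, by = 0.2), seed = 3)
  part <- out$partition
  expect_equal(length(unique(part)), 2)
  expect_equal(unname(lengths(split(names(part), part))[order(-lengths(split(names(part), part)))]),
               c(9L, 7L))
})
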