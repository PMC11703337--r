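test_that("compactness matches closed forms and a BFS oracle", {
  k6 <- clique_graph(6)
  expect_equal(compactness(k6, 1), 1 / log(6))
  expect_equal(compactness(k6, 2), 1 / log(6)^2)
  p3 <- cell_graph(data.frame(from = c("a", "b"), to = c("b", "c"), weight = 1),
                   nodes = c("a", "b", "c"), stage = "final")
  expect_equal(compactness(p3, 1), (4 / 3) / log(3))
  expect_equal(compactness(p3, 0), 4 / 3) # alpha = 0 is the raw mean SPD

  set.seed(91)
  for (rep in 1:8) {
    n <- sample(10:50, 1)
    repeat { # keep drawing until connected
      edges <- random_graph_edges(n, 2.2 / n)
      g <- cell_graph(data.frame(from = edges[, 1], to = edges[, 2], weight = 1),
                      nodes = sprintf("c%02d", seq_len(n)), stage = "final")
      if (igraph::components(g$graph)$no == 1) break
    }
    oracle <- bfs_mean_spd(edges, sprintf("c%02d", seq_len(n)))
    expect_equal(compactness(g, 0), oracle, tolerance = 1e-12)
  }

  expect_error(compactness(clique_graph(c(3, 3)), 1), "disconnected")
})

test_that("alpha calibration: complete graph gives 0; fixed seed reproduces", {
  k12 <- clique_graph(12)
  cal <- calibrate_alpha(k12, seed = 4)
  expect_equal(cal$alpha, 0)
  set.seed(92)
  edges <- random_graph_edges(40, 0.12)
  g <- cell_graph(data.frame(from = edges[, 1], to = edges[, 2], weight = 1),
                  nodes = sprintf("c%02d", 1:40), stage = "final")
  c1 <- calibrate_alpha(g, seed = 7)
  c2 <- calibrate_alpha(g, seed = 7)
  expect_identical(c1, c2)
  expect_lt(c1$alpha, 2)
})

test_that("intra-cluster connectivity follows e_cc / e_c", {
  g <- clique_graph(c(5, 5), bridges = cbind("c01", "c06"))
  all_cells <- igraph::V(g$graph)$name
  expect_equal(intra_cluster_connectivity(g, all_cells), 1)
  # single node of positive degree has no internal edges
  expect_equal(intra_cluster_connectivity(g, "c01"), 0)
  # clique of 5 (10 internal) plus the bridge boundary edge
  expect_equal(intra_cluster_connectivity(g, sprintf("c%02d", 1:5)), 10 / 11)
  # hand instance: 4 internal, 1 boundary
  g2 <- cell_graph(data.frame(from = c("a", "a", "b", "c", "d"),
                              to = c("b", "c", "c", "d", "x"), weight = 1),
                   nodes = c("a", "b", "c", "d", "x"), stage = "final")
  expect_equal(intra_cluster_connectivity(g2, c("a", "b", "c", "d")), 4 / 5)
})

test_that("permutation p-values: exhaustive enumeration on a two-clique instance", {
  g <- clique_graph(c(6, 6))
  nodes <- igraph::V(g$graph)$name
  children <- setNames(rep(c("A", "B"), each = 6), nodes)
  p <- lambda_permutation_test(g, children, n_perm = 100, seed = 13)
  # exhaustive check: 10% of 12 cells -> 2 moved, each forced to the other
  # child; for every one of the C(12,2) selections both cliques lose lambda
  lam_child <- function(lab, child) {
    e <- igraph::as_edgelist(g$graph)
    in1 <- lab[e[, 1]] == child
    in2 <- lab[e[, 2]] == child
    if (!any(in1 | in2)) 0 else sum(in1 & in2) / sum(in1 | in2)
  }
  worst <- 1
  for (pair in combn(12, 2, simplify = FALSE)) {
    lab <- children
    lab[pair] <- ifelse(lab[pair] == "A", "B", "A")
    worst <- min(worst, 1) # keep loop explicit
    expect_lt(lam_child(lab, "A"), 1)
    expect_lt(lam_child(lab, "B"), 1)
  }
  # hence the attainable minimum p for both children
  expect_equal(unname(p["A"]), 1 / 101)
  expect_equal(unname(p["B"]), 1 / 101)
  expect_equal(unname(attr(p, "lambda_obs")), c(1, 1))

  expect_error(lambda_permutation_test(g, children, n_perm = 0), "n_perm")
  expect_error(lambda_permutation_test(g, setNames(rep("A", 12), nodes)),
               "2 child")
})

test_that("random children on a homogeneous graph are not significant", {
  set.seed(14)
  edges <- random_graph_edges(30, 0.3)
  g <- cell_graph(data.frame(from = edges[, 1], to = edges[, 2], weight = 1),
                  nodes = sprintf("c%02d", 1:30), stage = "final")
  children <- setNames(sample(c("A", "B"), 30, replace = TRUE),
                       sprintf("c%02d", 1:30))
  p <- lambda_permutation_test(g, children, n_perm = 200, seed = 15)
  expect_gt(min(p), 0.05)
})

test_that("split gating accepts real structure and rejects noise", {
  g <- clique_graph(c(10, 10))
  nodes <- igraph::V(g$graph)$name
  truth <- setNames(rep(c("A", "B"), each = 10), nodes)
  ev <- evaluate_split(g, truth, alpha = 1, seed = 16)
  expect_true(all(ev$accepted))
  expect_true(all(ev$v_child < ev$v_parent))

  # random bisection of one clique: no compactness gain, lambda ~ 0.5
  k20 <- clique_graph(20)
  nodes2 <- igraph::V(k20$graph)$name
  noise <- setNames(rep(c("A", "B"), 10), nodes2)
  ev2 <- evaluate_split(k20, noise, alpha = 1, seed = 17)
  expect_false(any(ev2$accepted))

  # minimum size rule dominates the metrics
  small <- setNames(c(rep("A", 17), rep("B", 3)), nodes2)
  ev3 <- evaluate_split(k20, small, alpha = 1, min_cluster_size = 10, seed = 18)
  expect_false(ev3$accepted[ev3$child == "B"])
})

test_that("two disconnected cliques become two terminal roots", {
  g <- clique_graph(c(25, 25))
  h <- run_msc(g, msc_config(seed = 19))
  expect_equal(sum(h$nodes$parent == "root"), 2)
  expect_equal(nrow(h$nodes), 2) # no improving split inside a clique
  expect_true(all(h$nodes$is_leaf))
  expect_length(h$unassigned, 0)
})

test_that("hierarchy invariants: nesting, disjoint siblings, determinism", {
  spec <- scenario_spec("II", inner_sizes = rep(20L, 4),
                        outer_grouping = rep(1:2, each = 2),
                        rho_in = 0.4, delta_rho = 0.2, sigma = 0.3,
                        n_features = 300, seed = 23)
  sim <- simulate_dataset(spec)
  res <- run_pipeline(sim, config = msc_config(seed = 23))
  h <- res$hierarchy
  for (i in seq_len(nrow(h$nodes))) {
    p <- h$nodes$parent[i]
    if (p != "root") {
      expect_true(all(h$cells[[h$nodes$id[i]]] %in% h$cells[[p]]))
    }
  }
  for (p in unique(h$nodes$parent)) {
    kids <- h$nodes$id[h$nodes$parent == p]
    if (length(kids) > 1) {
      all_kid_cells <- unlist(h$cells[kids], use.names = FALSE)
      expect_false(anyDuplicated(all_kid_cells) > 0)
    }
  }
  expect_true(all(h$nodes$size[h$nodes$parent != "root"] <
                    h$nodes$size[match(h$nodes$parent[h$nodes$parent != "root"],
                                       h$nodes$id)]))
  res2 <- run_pipeline(sim, config = msc_config(seed = 23))
  expect_identical(h$nodes, res2$hierarchy$nodes)
  expect_identical(h$cells, res2$hierarchy$cells)
})

test_that("well-separated blocks are recovered at high Jaccard", {
  spec <- scenario_spec("I", inner_sizes = c(30L, 30L, 40L),
                        rho_in = 0.8, sigma = 1, n_features = 500, seed = 29)
  sim <- simulate_dataset(spec)
  res <- run_pipeline(sim, config = msc_config(seed = 29))
  da <- detection_accuracy(hierarchy_clusters(res$hierarchy),
                           truth_clusters(sim, "inner"))
  expect_true(all(da$per_cluster >= 0.9))
})
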