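# a raw_union graph whose edges' similarities sit exactly on a line in the
# expressed-jaccard, plus controllable outliers
make_line_instance <- function(n_edges = 100, outlier_rows = integer(0)) {
  n <- n_edges + 1
  # chain graph: edge k joins cells k and k+1
  from <- sprintf("c%03d", seq_len(n_edges))
  to <- sprintf("c%03d", seq_len(n_edges) + 1)
  # expression profiles: cell k expresses genes 1..(20 + k %% 30)
  ngene <- 60
  vals <- matrix(0, n, ngene)
  for (k in seq_len(n)) vals[k, seq_len(20 + k %% 30)] <- 1
  expr <- expression_matrix(vals, cell_ids = sprintf("c%03d", seq_len(n)))
  j <- msclust:::expressed_jaccard_edges(expr, from, to)
  wt <- 0.2 + 0.5 * j
  wt[outlier_rows] <- wt[outlier_rows] - 0.4
  g <- cell_graph(data.frame(from = from, to = to, weight = wt),
                  nodes = sprintf("c%03d", seq_len(n)),
                  stage = "raw_union", mode = "correlation")
  list(g = g, expr = expr, from = from, to = to)
}

test_that("edges on the fitted curve survive; a gross outlier is removed", {
  inst <- make_line_instance()
  out <- low_similarity_screen(inst$g, inst$expr)
  expect_equal(igraph::ecount(out$graph), igraph::ecount(inst$g$graph))
  expect_equal(out$stage, "similarity_screened")

  inst2 <- make_line_instance(outlier_rows = 37)
  out2 <- low_similarity_screen(inst2$g, inst2$expr)
  rep2 <- attr(out2, "screen_report")
  expect_equal(rep2$n_removed_similarity, 1L)
  gone <- setdiff(paste(graph_edges(inst2$g)$from, graph_edges(inst2$g)$to),
                  paste(graph_edges(out2)$from, graph_edges(out2)$to))
  expect_equal(gone, paste(inst2$from[37], inst2$to[37]))
})

test_that("the similarity screen is skipped in euclidean mode and on tiny graphs", {
  g <- clique_graph(c(4, 4), stage = "raw_union", mode = "neg_euclidean")
  expect_warning(out <- low_similarity_screen(g, NULL), "skipped")
  expect_equal(igraph::ecount(out$graph), igraph::ecount(g$graph))
  expect_equal(out$stage, "similarity_screened")

  g2 <- clique_graph(c(3, 3), stage = "raw_union")
  e2 <- expression_matrix(matrix(1, 6, 4),
                          cell_ids = igraph::V(g2$graph)$name)
  expect_warning(low_similarity_screen(g2, e2), "fewer than 30")
})

test_that("mutual neighbour ratio follows the set formula", {
  # N(i) = {j, a, b}, N(j) = {i, a, c} -> |{a}| / |{j,a,b,i,c}| = 0.2
  g <- cell_graph(data.frame(from = c("i", "i", "i", "j", "j"),
                             to = c("j", "a", "b", "a", "c"),
                             weight = 1),
                  nodes = c("i", "j", "a", "b", "c"), stage = "final")
  expect_equal(mutual_neighbor_ratio(g, "i", "j"), 0.2)
  # identical neighbourhoods of nonadjacent pair
  g2 <- cell_graph(data.frame(from = c("x", "x", "y", "y"),
                              to = c("a", "b", "a", "b"), weight = 1),
                   nodes = c("x", "y", "a", "b"), stage = "final")
  expect_equal(mutual_neighbor_ratio(g2, "x", "y"), 1)
  # adjacent pair with no shared neighbours
  g3 <- cell_graph(data.frame(from = c("u", "u", "v", "v", "u"),
                              to = c("p", "q", "r", "s", "v"), weight = 1),
                   nodes = c("u", "v", "p", "q", "r", "s"), stage = "final")
  expect_equal(mutual_neighbor_ratio(g3, "u", "v"), 0)
})

test_that("centrality screen never orphans cells and respects the quantile", {
  # star graph: no shared neighbours anywhere, removal never helps
  star <- cell_graph(data.frame(from = "hub", to = sprintf("s%d", 1:8),
                                weight = seq(0.1, 0.8, by = 0.1)),
                     nodes = c("hub", sprintf("s%d", 1:8)),
                     stage = "similarity_screened")
  out <- centrality_screen(star, contested_quantile = 1)
  expect_equal(igraph::ecount(out$graph), 8)
  expect_equal(out$stage, "final")

  # quantile zero leaves any graph untouched
  g <- clique_graph(c(5, 5), stage = "similarity_screened")
  expect_equal(igraph::ecount(centrality_screen(g, 0)$graph),
               igraph::ecount(g$graph))
})

test_that("redundant weak edges are pruned while bridges survive", {
  # a contested edge is removed iff its endpoints share neighbours (the edge
  # is redundant for local connectivity); a bridge shares none and stays
  g <- clique_graph(c(6, 6),
                    bridges = cbind("c01", "c07"),
                    stage = "similarity_screened")
  e <- graph_edges(g)
  bridge_row <- which(e$from == "c01" & e$to == "c07")
  weak_row <- which(e$from == "c02" & e$to == "c03")
  igraph::E(g$graph)$weight[bridge_row] <- 0.5
  igraph::E(g$graph)$weight[weak_row] <- 0.05
  out <- centrality_screen(g, contested_quantile = 2 / 31)
  e_out <- graph_edges(out)
  expect_true(any(e_out$from == "c01" & e_out$to == "c07"))   # bridge kept
  expect_false(any(e_out$from == "c02" & e_out$to == "c03"))  # redundant gone
  expect_equal(igraph::ecount(out$graph), igraph::ecount(g$graph) - 1)
})

test_that("triangle edges are pruned down to a path, never orphaning", {
  tri <- cell_graph(data.frame(from = c("a", "a", "b"),
                               to = c("b", "c", "c"),
                               weight = c(0.2, 0.5, 0.8)),
                    nodes = c("a", "b", "c"), stage = "similarity_screened")
  out <- centrality_screen(tri, contested_quantile = 1)
  # lowest edge (a,b) removed: the pair keeps shared neighbour c over a
  # smaller union; remaining path edges have no shared neighbours
  expect_equal(igraph::ecount(out$graph), 2)
  expect_true(all(igraph::degree(out$graph) >= 1))
})

test_that("screens only delete edges; weights and nodes are preserved", {
  set.seed(61)
  x <- matrix(rpois(30 * 50, 2), 30, 50) # zeros make the expressed sets vary
  expr <- expression_matrix(x)
  sim <- pearson_similarity(expr)
  g <- build_len(sim)
  out <- screen_edges(g, expr)
  e_in <- graph_edges(g)
  e_out <- graph_edges(out)
  expect_true(all(paste(e_out$from, e_out$to) %in% paste(e_in$from, e_in$to)))
  merged <- merge(e_out, e_in, by = c("from", "to"))
  expect_equal(merged$weight.x, merged$weight.y)
  expect_identical(sort(igraph::V(out$graph)$name),
                   sort(igraph::V(g$graph)$name))
  # determinism
  out2 <- screen_edges(g, expr)
  expect_identical(graph_edges(out), graph_edges(out2))
})
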