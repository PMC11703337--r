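#' Cell graph container
#'
#' A weighted undirected cell-cell network at a given processing stage:
#' `"raw_union"` (union of per-cell locally embedded graphs),
#' `"similarity_screened"` (after the LOESS low-similarity screen) or
#' `"final"` (after the centrality screen). Backed by an igraph object whose
#' vertex names are cell ids and whose `weight` edge attribute is the
#' similarity.
#'
#' @param edges data frame with columns `from`, `to`, `weight`.
#' @param nodes character vector of all cell ids (isolated cells allowed).
#' @param stage processing stage label.
#' @param mode similarity mode the weights came from.
#' @return A `cell_graph`.
#' @export
cell_graph <- function(edges, nodes, stage = "raw_union", mode = "correlation") {
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  if (!all(is.finite(edges$weight))) stop("edge weights must be finite")
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(list(graph = g, stage = stage, mode = mode), class = "cell_graph")
}

as_cell_graph <- function(g, stage, mode) {
  structure(list(graph = g, stage = stage, mode = mode), class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  n <- igraph::vcount(x$graph)
  m <- igraph::ecount(x$graph)
  cat(sprintf("cell graph [%s]: %d cells, %d edges (m/N = %.2f), mode = %s\n",
              x$stage, n, m, if (n > 0) m / n else NA_real_, x$mode))
  invisible(x)
}

#' Number of edges per cell (sparsity factor)
#'
#' @param g a `cell_graph`.
#' @return `m / N`, the edge-per-node ratio.
#' @export
sparsity_factor <- function(g) {
  igraph::ecount(g$graph) / igraph::vcount(g$graph)
}

#' Edge list of a cell graph
#'
#' @param g a `cell_graph`.
#' @return Data frame with `from`, `to`, `weight`.
#' @export
graph_edges <- function(g) {
  e <- igraph::as_data_frame(g$graph, what = "edges")
  names(e)[1:2] <- c("from", "to")
  e
}

#' Exact planarity test
#'
#' Left-right (de Fraysseix-Rosenstiehl) planarity criterion; exact, not
#' heuristic.
#'
#' @param x a `cell_graph`, an igraph object, or a 2-column integer edge
#'   matrix (1-based vertex indices; supply `n`).
#' @param n number of vertices when `x` is an edge matrix.
#' @return `TRUE` iff the graph is planar.
#' @export
is_planar <- function(x, n = NULL) {
  if (inherits(x, "cell_graph")) x <- x$graph
  if (inherits(x, "igraph")) {
    n <- igraph::vcount(x)
    e <- igraph::as_edgelist(x, names = FALSE)
    storage.mode(e) <- "integer"
    return(lr_is_planar(n, e))
  }
  if (is.null(n)) stop("supply n for an edge-matrix input")
  e <- as.matrix(x)
  storage.mode(e) <- "integer"
  lr_is_planar(as.integer(n), e)
}

# Greedy PMFG over a weight matrix restricted to `idx` (global indices used
# for the deterministic tie-break). Returns the accepted edge list in global
# indices.
pmfg_edges <- function(w, idx = seq_len(nrow(w))) {
  s <- length(idx)
  if (s < 2) return(cbind(integer(0), integer(0)))
  pr <- which(upper.tri(matrix(0, s, s)), arr.ind = TRUE)
  gi <- idx[pr[, 1]]
  gj <- idx[pr[, 2]]
  a <- pmin(gi, gj)
  b <- pmax(gi, gj)
  wt <- w[cbind(gi, gj)]
  o <- order(-wt, a, b)
  keep <- pmfg_accept(s, pr[o, 1], pr[o, 2])
  cbind(a[o][keep], b[o][keep])
}

#' Planar maximally filtered graph of a similarity matrix
#'
#' Inserts candidate edges in decreasing similarity (ties broken by the
#' smaller, then larger, cell index) and keeps an edge iff the graph stays
#' planar, stopping at the Euler bound of `3(N - 2)` edges. For `N <= 4` the
#' result is the complete graph.
#'
#' @param sim an `msc_similarity` or a symmetric numeric matrix.
#' @param nodes optional subset of cell ids or indices.
#' @return A planar `cell_graph` (stage `"local"`).
#' @export
pmfg <- function(sim, nodes = NULL) {
  mode <- if (inherits(sim, "msc_similarity")) sim$mode else "correlation"
  w <- if (inherits(sim, "msc_similarity")) sim$values else as.matrix(sim)
  if (is.null(rownames(w))) {
    rownames(w) <- colnames(w) <- sprintf("cell_%04d", seq_len(nrow(w)))
  }
  idx <- if (is.null(nodes)) seq_len(nrow(w)) else {
    if (is.character(nodes)) match(nodes, rownames(w)) else as.integer(nodes)
  }
  if (anyNA(idx)) stop("unknown node ids")
  if (length(idx) < 2) stop("need >= 2 nodes")
  e <- pmfg_edges(w, idx)
  ids <- rownames(w)
  cell_graph(data.frame(from = ids[e[, 1]], to = ids[e[, 2]],
                        weight = w[e]),
             nodes = ids[sort(idx)], stage = "local", mode = mode)
}
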