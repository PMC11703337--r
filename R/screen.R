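#' Low-similarity edge screen (LOESS outliers)
#'
#' The proportion of commonly expressed genes between two cells (expressed-set
#' Jaccard, J) modulates how high a correlation can be expected from them;
#' sparsity-driven noisy links show up as similarities far below that
#' expectation. The screen fits similarity as a smooth function of J by LOESS
#' and removes edges more than two residual standard deviations below the
#' fitted mean. One-sided: only low-similarity outliers are removed.
#'
#' Applies only to correlation-mode graphs; in negated-Euclidean mode the
#' graph is returned unchanged with a warning (J is an expression-space
#' quantity). Skipped with a warning when there are fewer than 30 edges or J
#' is constant.
#'
#' @param g a `cell_graph` at stage `"raw_union"`.
#' @param expr the `msc_expr` the similarities came from.
#' @param span LOESS span (default 0.5); an ill-conditioned smoother falls
#'   back to an ordinary linear fit.
#' @return A `cell_graph` at stage `"similarity_screened"`, with a
#'   `screen_report` attribute.
#' @export
low_similarity_screen <- function(g, expr, span = 0.5) {
  stopifnot(inherits(g, "cell_graph"))
  if (g$stage != "raw_union") stop("expected a raw_union graph")
  e <- graph_edges(g)
  report <- list(n_edges_in = nrow(e), n_removed_similarity = 0L,
                 skipped = FALSE, reason = NULL)
  skip <- function(reason) {
    warning("low-similarity screen skipped: ", reason)
    report$skipped <<- TRUE
    report$reason <<- reason
  }
  if (g$mode != "correlation") {
    skip("similarity mode is not expression-based correlation")
  } else if (nrow(e) < 30) {
    skip("fewer than 30 edges")
  } else {
    stopifnot(inherits(expr, "msc_expr"))
    j <- expressed_jaccard_edges(expr, e$from, e$to)
    if (length(unique(j)) == 1) {
      skip("constant expressed-gene jaccard")
    } else {
      fit_vals <- tryCatch({
        fit <- suppressWarnings(loess(e$weight ~ j, span = span,
                                      degree = 2, family = "gaussian"))
        fv <- predict(fit, data.frame(j = j))
        if (anyNA(fv)) stop("loess produced NA")
        fv
      }, error = function(err) {
        lfit <- lm(e$weight ~ j)
        predict(lfit, data.frame(j = j))
      })
      resid <- e$weight - fit_vals
      s <- sd(resid)
      drop_edge <- if (s > 0) e$weight < fit_vals - 2 * s else rep(FALSE, nrow(e))
      report$n_removed_similarity <- sum(drop_edge)
      report$loess_fit <- data.frame(jaccard = j, fitted = fit_vals,
                                     residual = resid)
      report$residual_sd <- s
      if (any(drop_edge)) {
        g$graph <- igraph::delete_edges(g$graph, which(drop_edge))
      }
    }
  }
  g$stage <- "similarity_screened"
  attr(g, "screen_report") <- report
  g
}

#' Shared-neighbour ratio of a cell pair
#'
#' `M_ij = |N(i) intersect N(j)| / |N(i) union N(j)|` over the current
#' adjacency (open neighbourhoods); 0 when the union is empty.
#'
#' @param g a `cell_graph`.
#' @param i,j cell ids.
#' @return A number in `[0, 1]`.
#' @export
mutual_neighbor_ratio <- function(g, i, j) {
  stopifnot(inherits(g, "cell_graph"))
  ni <- igraph::neighbors(g$graph, i)$name
  nj <- igraph::neighbors(g$graph, j)$name
  u <- union(ni, nj)
  if (length(u) == 0) return(0)
  length(intersect(ni, nj)) / length(u)
}

mnr_sets <- function(ni, nj) {
  u <- length(union(ni, nj))
  if (u == 0) return(0)
  length(intersect(ni, nj)) / u
}

#' Low-centrality edge screen (shared-neighbour contest)
#'
#' Edges in the lowest `contested_quantile` by similarity are visited in
#' ascending similarity order; a contested edge (i, j) is removed iff the
#' shared-neighbour ratio M_ij computed without the edge strictly exceeds the
#' ratio with it, and neither endpoint would be orphaned. Removals take effect
#' immediately, so later contests see the updated graph.
#'
#' @param g a `cell_graph` at stage `"similarity_screened"`.
#' @param contested_quantile fraction of lowest-similarity edges contested
#'   (default 0.25).
#' @return A `cell_graph` at stage `"final"`, with a `screen_report`
#'   attribute.
#' @export
centrality_screen <- function(g, contested_quantile = 0.25) {
  stopifnot(inherits(g, "cell_graph"))
  if (g$stage != "similarity_screened") stop("expected a similarity_screened graph")
  stopifnot(contested_quantile >= 0, contested_quantile <= 1)
  e <- graph_edges(g)
  m <- nrow(e)
  n_contest <- floor(contested_quantile * m)
  removed <- 0L
  if (n_contest > 0) {
    # adjacency as named list of neighbour id vectors
    adj <- lapply(igraph::adjacent_vertices(g$graph, igraph::V(g$graph)),
                  function(v) v$name)
    names(adj) <- igraph::V(g$graph)$name
    o <- order(e$weight, pmin(e$from, e$to), pmax(e$from, e$to))
    contested <- o[seq_len(n_contest)]
    drop_rows <- integer(0)
    for (r in contested) {
      i <- e$from[r]; j <- e$to[r]
      ni <- adj[[i]]; nj <- adj[[j]]
      if (length(ni) <= 1 || length(nj) <= 1) next # degree guard
      m_with <- mnr_sets(ni, nj)
      m_without <- mnr_sets(setdiff(ni, j), setdiff(nj, i))
      if (m_without > m_with) {
        adj[[i]] <- setdiff(ni, j)
        adj[[j]] <- setdiff(nj, i)
        drop_rows <- c(drop_rows, r)
        removed <- removed + 1L
      }
    }
    if (length(drop_rows)) {
      g$graph <- igraph::delete_edges(g$graph, drop_rows)
    }
  }
  prev <- attr(g, "screen_report")
  report <- list(n_edges_in = m, n_removed_centrality = removed,
                 contested_quantile = contested_quantile,
                 n_edges_out = m - removed,
                 n_components = igraph::components(g$graph)$no,
                 similarity_screen = prev)
  g$stage <- "final"
  attr(g, "screen_report") <- report
  g
}

#' Run both edge screens
#'
#' [low_similarity_screen()] followed by [centrality_screen()].
#'
#' @inheritParams low_similarity_screen
#' @inheritParams centrality_screen
#' @param skip_similarity_screen skip the LOESS screen (it is also skipped
#'   automatically in negated-Euclidean mode).
#' @return A `cell_graph` at stage `"final"`.
#' @export
screen_edges <- function(g, expr = NULL, span = 0.5, contested_quantile = 0.25,
                         skip_similarity_screen = FALSE) {
  if (skip_similarity_screen || g$mode != "correlation") {
    if (g$mode == "correlation" && skip_similarity_screen) {
      g$stage <- "similarity_screened"
      attr(g, "screen_report") <- list(n_edges_in = igraph::ecount(g$graph),
                                       n_removed_similarity = 0L,
                                       skipped = TRUE, reason = "user request")
    } else {
      g <- suppressWarnings(low_similarity_screen(g, expr, span = span))
    }
  } else {
    g <- low_similarity_screen(g, expr, span = span)
  }
  centrality_screen(g, contested_quantile = contested_quantile)
}
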