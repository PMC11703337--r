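#' Locally embedded neighbours of one cell
#'
#' Grows the neighbourhood size k from 3 upward; at each k a planar maximally
#' filtered graph is built on the cell plus its k most similar cells, and the
#' cells adjacent to the focal cell are recorded. The adjacency set typically
#' saturates around `k ~ log(N)`; growth stops once the set is unchanged for
#' `stall` consecutive increments (or `k_max` is reached), and the stabilised
#' set is returned as the embedded nearest neighbours.
#'
#' @param cell cell id or index.
#' @param sim an `msc_similarity`.
#' @param stall number of consecutive unchanged increments that defines the
#'   plateau (default 3).
#' @param k_max largest neighbourhood size; default
#'   `max(10, ceiling(3 * log(N)))`, capped at `N - 1`.
#' @param trace keep the per-k adjacency sets for diagnostics.
#' @return A `neighbor_result` with `cell`, `neighbors`, `k_saturation` and
#'   optionally `trace`.
#' @export
local_embedding <- function(cell, sim, stall = 3L, k_max = NULL, trace = FALSE) {
  stopifnot(inherits(sim, "msc_similarity"))
  w <- sim$values
  n <- nrow(w)
  ids <- rownames(w)
  i <- if (is.character(cell)) match(cell, ids) else as.integer(cell)
  if (is.na(i)) stop("unknown cell: ", cell)
  if (n < 2) stop("need at least two cells")
  others <- setdiff(seq_len(n), i)
  # similarity-descending order with deterministic index tie-break
  ord <- others[order(-w[i, others], others)]
  res <- list(cell = ids[i])
  if (length(others) <= 3) {
    res$neighbors <- ids[sort(ord)]
    res$k_saturation <- length(ord)
    res$trace <- if (trace) list(ids[sort(ord)]) else NULL
    class(res) <- "neighbor_result"
    return(res)
  }
  if (is.null(k_max)) k_max <- max(10L, ceiling(3 * log(n)))
  k_max <- min(as.integer(k_max), n - 1L)
  prev <- NULL
  unchanged <- 0L
  k_stable <- 3L
  tr <- if (trace) list() else NULL
  for (k in 3:k_max) {
    idx <- c(i, ord[seq_len(k)])
    e <- pmfg_edges(w, idx)
    nn <- sort(unique(c(e[e[, 1] == i, 2], e[e[, 2] == i, 1])))
    if (trace) tr[[length(tr) + 1L]] <- ids[nn]
    if (!is.null(prev) && identical(nn, prev)) {
      unchanged <- unchanged + 1L
      if (unchanged >= stall) break
    } else {
      unchanged <- 0L
      k_stable <- k
    }
    prev <- nn
  }
  res$neighbors <- ids[prev]
  res$k_saturation <- k_stable
  res$trace <- tr
  class(res) <- "neighbor_result"
  res
}

#' @export
print.neighbor_result <- function(x, ...) {
  cat(sprintf("embedded neighbours of %s (k' = %d): %s\n", x$cell,
              x$k_saturation, paste(x$neighbors, collapse = ", ")))
  invisible(x)
}

#' Assemble the raw locally embedded network
#'
#' Union over cells of the edges from each cell to its embedded neighbours:
#' edge (i, j) is present iff j is a neighbour of i or i a neighbour of j.
#'
#' @param results list of `neighbor_result`, one per cell.
#' @param sim the `msc_similarity` the embeddings came from.
#' @return A `cell_graph` at stage `"raw_union"`.
#' @export
assemble_len <- function(results, sim) {
  stopifnot(inherits(sim, "msc_similarity"))
  ids <- rownames(sim$values)
  from <- rep(vapply(results, `[[`, "", "cell"),
              vapply(results, function(r) length(r$neighbors), 0L))
  to <- unlist(lapply(results, `[[`, "neighbors"), use.names = FALSE)
  a <- pmin(from, to)
  b <- pmax(from, to)
  keep <- !duplicated(paste(a, b))
  a <- a[keep]
  b <- b[keep]
  wt <- sim$values[cbind(match(a, ids), match(b, ids))]
  o <- order(a, b)
  cell_graph(data.frame(from = a[o], to = b[o], weight = wt[o]),
             nodes = ids, stage = "raw_union", mode = sim$mode)
}

#' Build the raw locally embedded network for all cells
#'
#' Runs [local_embedding()] for every cell and unions the results.
#'
#' @inheritParams local_embedding
#' @param sim an `msc_similarity`.
#' @param verbose print progress every 200 cells.
#' @return A `cell_graph` at stage `"raw_union"`.
#' @export
build_len <- function(sim, stall = 3L, k_max = NULL, verbose = FALSE) {
  ids <- rownames(sim$values)
  results <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    results[[i]] <- local_embedding(i, sim, stall = stall, k_max = k_max)
    if (verbose && i %% 200 == 0) message("  embedded ", i, "/", length(ids), " cells")
  }
  assemble_len(results, sim)
}
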