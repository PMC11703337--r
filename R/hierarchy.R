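#' Cluster compactness
#'
#' `v(alpha) = SPDbar / log(Nc)^alpha`, where SPDbar is the mean unweighted
#' shortest-path distance over all unordered node pairs and Nc the node count.
#' Smaller is more compact. Natural logarithm throughout.
#'
#' @param subgraph connected `cell_graph` or igraph with >= 3 nodes.
#' @param alpha compactness scaling parameter (see [calibrate_alpha()]).
#' @return The compactness value.
#' @export
compactness <- function(subgraph, alpha) {
  ig <- as_igraph(subgraph)
  n <- igraph::vcount(ig)
  if (n < 3) stop("compactness needs >= 3 nodes")
  if (igraph::components(ig)$no > 1) {
    stop("subgraph is disconnected; compute per component")
  }
  mean_spd(ig) / log(n)^alpha
}

mean_spd <- function(ig) {
  d <- igraph::distances(ig, weights = NA)
  mean(d[upper.tri(d)])
}

# size-weighted mean compactness over connected components (components of
# fewer than 3 nodes contribute their size with v = 0 distance i.e. SPD of a
# pair is 1, of a singleton 0)
compactness_components <- function(ig, alpha) {
  comp <- igraph::components(ig)
  vs <- igraph::V(ig)$name
  total <- 0
  for (c in seq_len(comp$no)) {
    members <- vs[comp$membership == c]
    nc <- length(members)
    v <- if (nc >= 3) {
      compactness(igraph::induced_subgraph(ig, members), alpha)
    } else if (nc == 2) {
      1 / log(2)^alpha # single edge: SPDbar = 1
    } else {
      0
    }
    total <- total + nc * v
  }
  total / igraph::vcount(ig)
}

#' Calibrate the compactness scaling parameter
#'
#' Samples `n_samples` subnetworks as 3-hop neighbourhoods of randomly chosen
#' nodes and computes the reference scaling
#' `alpha0 = log(SPDbar) / log(log(Nc))` for each sample with at least 4
#' nodes; the calibrated alpha is the median. Falls back to `alpha = 1` when
#' fewer than 10 samples are valid, and warns when the calibrated value
#' reaches 2 (planar neighbourhood growth should keep it below 2).
#'
#' @param g a `cell_graph` or igraph with >= 10 nodes.
#' @param n_samples number of sampled roots (default 100).
#' @param n_layers neighbourhood radius in hops (default 3).
#' @param seed RNG seed.
#' @return List with `alpha`, `alpha_samples` and `n_valid`.
#' @export
calibrate_alpha <- function(g, n_samples = 100L, n_layers = 3L, seed = 1L) {
  ig <- as_igraph(g)
  n <- igraph::vcount(ig)
  if (n < 10) stop("alpha calibration needs >= 10 nodes")
  a0 <- local_seed(seed, {
    roots <- sample(seq_len(n), n_samples, replace = n < n_samples)
    vapply(roots, function(r) {
      nb <- igraph::ego(ig, order = n_layers, nodes = r)[[1]]
      nc <- length(nb)
      if (nc < 4) return(NA_real_)
      spd <- mean_spd(igraph::induced_subgraph(ig, nb))
      log(spd) / log(log(nc))
    }, numeric(1))
  })
  valid <- a0[is.finite(a0)]
  alpha <- if (length(valid) >= 10) median(valid) else 1
  if (alpha >= 2) {
    warning(sprintf("calibrated alpha = %.2f >= 2; unusual for planar-derived networks", alpha))
  }
  list(alpha = alpha, alpha_samples = a0, n_valid = length(valid))
}

#' Intra-cluster connectivity of a child cluster
#'
#' `lambda = e_cc / e_c`: internal edges of the child over all parent edges
#' touching the child; 0 when the child touches no edge.
#'
#' @param parent_graph `cell_graph` or igraph of the parent cluster.
#' @param child_cells nonempty subset of the parent's cells.
#' @return A number in `[0, 1]`.
#' @export
intra_cluster_connectivity <- function(parent_graph, child_cells) {
  ig <- as_igraph(parent_graph)
  stopifnot(length(child_cells) > 0)
  if (!all(child_cells %in% igraph::V(ig)$name)) {
    stop("child_cells must be nodes of the parent graph")
  }
  ends <- igraph::as_edgelist(ig, names = TRUE)
  if (nrow(ends) == 0) return(0)
  in1 <- ends[, 1] %in% child_cells
  in2 <- ends[, 2] %in% child_cells
  e_c <- sum(in1 | in2)
  if (e_c == 0) return(0)
  sum(in1 & in2) / e_c
}

lambda_all_children <- function(ends_in1, ends_in2) {
  # helper on precomputed logical membership matrices (edges x children)
  e_c <- colSums(ends_in1 | ends_in2)
  e_cc <- colSums(ends_in1 & ends_in2)
  ifelse(e_c == 0, 0, e_cc / e_c)
}

#' Permutation test of intra-cluster connectivity
#'
#' Each permutation selects `ceiling(frac * n)` of the parent's cells
#' uniformly at random and moves every selected cell across clusters: it is
#' reassigned to a child drawn uniformly among the other children. Per child,
#' the p-value is `(1 + #{lambda_perm >= lambda_obs}) / (1 + n_perm)`.
#'
#' @param parent_graph `cell_graph` or igraph of the parent cluster.
#' @param children named membership vector (child id per parent cell) with at
#'   least two distinct children.
#' @param n_perm number of permutations (default 100, must be >= 1).
#' @param frac fraction of cells moved per permutation (default 0.10).
#' @param seed RNG seed.
#' @return Named vector of per-child p-values, with the observed lambdas as
#'   attribute `"lambda_obs"`.
#' @export
lambda_permutation_test <- function(parent_graph, children, n_perm = 100L,
                                    frac = 0.10, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  ig <- as_igraph(parent_graph)
  nodes <- igraph::V(ig)$name
  if (!all(nodes %in% names(children))) stop("children must cover the parent's cells")
  children <- children[nodes]
  ids <- sort(unique(as.character(children)))
  if (length(ids) < 2) stop("no split: need >= 2 child clusters")
  ends <- igraph::as_edgelist(ig, names = TRUE)
  obs_lab <- as.character(children)
  names(obs_lab) <- nodes
  lam <- function(lab) {
    l1 <- lab[ends[, 1]]
    l2 <- lab[ends[, 2]]
    vapply(ids, function(cid) {
      in1 <- l1 == cid
      in2 <- l2 == cid
      e_c <- sum(in1 | in2)
      if (e_c == 0) 0 else sum(in1 & in2) / e_c
    }, numeric(1))
  }
  lambda_obs <- lam(obs_lab)
  n_move <- min(length(nodes), max(2L, ceiling(frac * length(nodes))))
  exceed <- setNames(numeric(length(ids)), ids)
  local_seed(seed, {
    for (p in seq_len(n_perm)) {
      lab <- obs_lab
      sel <- sample(length(nodes), n_move)
      lab[sel] <- vapply(lab[sel], function(cur) {
        others <- ids[ids != cur]
        if (length(others) == 1) others else sample(others, 1)
      }, "")
      exceed <- exceed + (lam(lab) >= lambda_obs - 1e-12)
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  attr(p, "lambda_obs") <- lambda_obs
  p
}

#' Gate candidate child clusters against their parent
#'
#' A candidate is accepted iff (a) it has at least `min_cluster_size` cells
#' and is strictly smaller than the parent, (b) its compactness (size-weighted
#' over connected components) strictly improves on the parent's — a
#' disconnected parent counts as infinitely non-compact — and (c) its
#' intra-cluster connectivity is permutation-significant (p < `p_threshold`).
#'
#' @param parent_subgraph `cell_graph` or igraph of the parent cluster.
#' @param partition named membership vector of candidate children (>= 2
#'   distinct values).
#' @param alpha compactness scaling from [calibrate_alpha()].
#' @param min_cluster_size smallest acceptable child (default 10).
#' @param n_perm,frac,p_threshold permutation-test parameters.
#' @param seed RNG seed.
#' @return Data frame with one row per candidate: `child`, `size`, `v_parent`,
#'   `v_child`, `lambda`, `p_value`, `accepted`, plus the cell lists as the
#'   `"cells"` attribute.
#' @export
evaluate_split <- function(parent_subgraph, partition, alpha,
                           min_cluster_size = 10L, n_perm = 100L, frac = 0.10,
                           p_threshold = 0.05, seed = 1L) {
  ig <- as_igraph(parent_subgraph)
  nodes <- igraph::V(ig)$name
  stopifnot(all(nodes %in% names(partition)))
  partition <- partition[nodes]
  cand <- split(nodes, as.character(partition))
  if (length(cand) < 2) stop("need >= 2 candidate children")
  # a disconnected parent has no defined mean shortest-path distance, so any
  # finite-compactness child improves on it
  v_parent <- if (igraph::components(ig)$no > 1) Inf
              else compactness_components(ig, alpha)
  pvals <- lambda_permutation_test(ig, partition, n_perm = n_perm,
                                   frac = frac, seed = seed)
  lambda_obs <- attr(pvals, "lambda_obs")
  res <- data.frame(child = names(cand),
                    size = vapply(cand, length, 0L),
                    v_parent = v_parent,
                    v_child = NA_real_,
                    lambda = lambda_obs[names(cand)],
                    p_value = pvals[names(cand)],
                    row.names = NULL)
  for (k in seq_len(nrow(res))) {
    cells <- cand[[res$child[k]]]
    if (length(cells) >= 2) {
      res$v_child[k] <- compactness_components(
        igraph::induced_subgraph(ig, cells), alpha)
    }
  }
  res$accepted <- res$size >= min_cluster_size &
    res$size < length(nodes) &
    !is.na(res$v_child) & res$v_child < res$v_parent &
    res$p_value < p_threshold
  attr(res, "cells") <- cand
  res
}

#' MSC run configuration
#'
#' @param gammas resolution grid for [scan_resolutions()].
#' @param min_cluster_size smallest cluster reported (default 10).
#' @param min_split_size smallest cluster that is considered for further
#'   splitting (default 20).
#' @param n_perm,perm_frac,p_threshold permutation-test parameters.
#' @param n_alpha_samples sampled subnetworks for alpha calibration.
#' @param n_iterations Leiden iterations per resolution.
#' @param seed single user seed; stage seeds are derived from it by fixed
#'   offsets.
#' @return A list of class `msc_config`.
#' @export
msc_config <- function(gammas = default_gamma_grid(), min_cluster_size = 10L,
                       min_split_size = 20L, n_perm = 100L, perm_frac = 0.10,
                       p_threshold = 0.05, n_alpha_samples = 100L,
                       n_iterations = 10L, seed = 1L) {
  structure(list(gammas = gammas, min_cluster_size = as.integer(min_cluster_size),
                 min_split_size = as.integer(min_split_size),
                 n_perm = as.integer(n_perm), perm_frac = perm_frac,
                 p_threshold = p_threshold,
                 n_alpha_samples = as.integer(n_alpha_samples),
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "msc_config")
}

#' Iterative top-down multi-scale clustering
#'
#' Connected components of the screened network with at least
#' `min_cluster_size` cells become top-level clusters (smaller components are
#' reported as unassigned). Every node with at least `min_split_size` cells is
#' split by [adapt_split()] on its induced subgraph; children are gated by
#' [evaluate_split()] and accepted children recurse. The compactness scaling
#' alpha is calibrated once per top-level component and reused down its
#' subtree. Cells of rejected candidates stay covered by the parent only.
#'
#' @param g_o a `cell_graph` at stage `"final"` (any stage is accepted, with
#'   a warning for non-final input).
#' @param config an [msc_config()].
#' @return An `msc_hierarchy`: `nodes` (id, parent, size, gamma_f, v, lambda,
#'   p_value, is_leaf), `cells` (per-node cell sets), `membership` (long
#'   cell/node table covering every node on each cell's path), `unassigned`,
#'   and per-root `alpha`.
#' @export
run_msc <- function(g_o, config = msc_config()) {
  stopifnot(inherits(g_o, "cell_graph"))
  ig <- g_o$graph
  if (igraph::vcount(ig) == 0) stop("empty graph")
  if (g_o$stage != "final") {
    warning("clustering a graph at stage '", g_o$stage, "' (expected 'final')")
  }
  comp <- igraph::components(ig)
  vs <- igraph::V(ig)$name
  comp_cells <- split(vs, comp$membership)
  sizes <- vapply(comp_cells, length, 0L)
  # deterministic root order: size descending, then smallest cell id
  ord <- order(-sizes, vapply(comp_cells, min, ""))
  comp_cells <- comp_cells[ord]
  sizes <- sizes[ord]
  keep <- sizes >= config$min_cluster_size
  unassigned <- unlist(comp_cells[!keep], use.names = FALSE)
  comp_cells <- comp_cells[keep]

  nodes <- list()
  cells <- list()
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("M%d", counter)
  }
  # queue entries: id, cells, root_index (for alpha), depth
  queue <- list()
  alphas <- numeric(0)
  for (r in seq_along(comp_cells)) {
    sub <- igraph::induced_subgraph(ig, comp_cells[[r]])
    alphas[r] <- if (length(comp_cells[[r]]) >= 10) {
      calibrate_alpha(sub, n_samples = config$n_alpha_samples,
                      seed = derive_seed(config$seed, "alpha", r))$alpha
    } else 1
    id <- new_id()
    nodes[[id]] <- data.frame(id = id, parent = "root",
                              size = length(comp_cells[[r]]),
                              gamma_f = NA_real_, v = NA_real_,
                              lambda = NA_real_, p_value = NA_real_,
                              is_leaf = TRUE)
    cells[[id]] <- comp_cells[[r]]
    queue[[length(queue) + 1L]] <- list(id = id, root = r)
  }
  split_counter <- 0L
  while (length(queue)) {
    item <- queue[[1]]
    queue <- queue[-1]
    node_cells <- cells[[item$id]]
    if (length(node_cells) < config$min_split_size) next
    sub <- igraph::induced_subgraph(ig, node_cells)
    alpha <- alphas[item$root]
    split_counter <- split_counter + 1L
    subcomp <- igraph::components(sub)
    if (subcomp$no > 1) {
      partition <- setNames(as.integer(subcomp$membership),
                            igraph::V(sub)$name)
      gamma_f <- NA_real_
    } else {
      asp <- adapt_split(sub, gammas = config$gammas,
                         seed = derive_seed(config$seed, "leiden", split_counter),
                         n_iterations = config$n_iterations)
      if (asp$no_split) next
      partition <- asp$partition
      gamma_f <- asp$gamma_f
    }
    if (length(unique(partition)) < 2) next
    ev <- evaluate_split(sub, partition, alpha,
                         min_cluster_size = config$min_cluster_size,
                         n_perm = config$n_perm, frac = config$perm_frac,
                         p_threshold = config$p_threshold,
                         seed = derive_seed(config$seed, "perm", split_counter))
    cand_cells <- attr(ev, "cells")
    acc <- which(ev$accepted)
    if (length(acc) == 0) next
    nodes[[item$id]]$is_leaf <- FALSE
    nodes[[item$id]]$gamma_f <- gamma_f
    for (k in acc) {
      id <- new_id()
      ch_cells <- sort(cand_cells[[ev$child[k]]])
      nodes[[id]] <- data.frame(id = id, parent = item$id,
                                size = ev$size[k], gamma_f = NA_real_,
                                v = ev$v_child[k], lambda = ev$lambda[k],
                                p_value = ev$p_value[k], is_leaf = TRUE)
      cells[[id]] <- ch_cells
      queue[[length(queue) + 1L]] <- list(id = id, root = item$root)
    }
  }
  node_df <- do.call(rbind, nodes)
  rownames(node_df) <- NULL
  # root-level compactness for completeness
  root_rows <- which(node_df$parent == "root")
  for (ri in seq_along(root_rows)) {
    r <- root_rows[ri]
    sub <- igraph::induced_subgraph(ig, cells[[node_df$id[r]]])
    node_df$v[r] <- compactness_components(sub, alphas[ri])
  }
  membership <- data.frame(
    cell_id = unlist(cells, use.names = FALSE),
    node_id = rep(names(cells), vapply(cells, length, 0L)),
    row.names = NULL)
  structure(list(nodes = node_df, cells = cells, membership = membership,
                 unassigned = unassigned, alpha = alphas, config = config),
            class = "msc_hierarchy")
}

#' @export
print.msc_hierarchy <- function(x, ...) {
  cat(sprintf("msc hierarchy: %d nodes (%d roots, %d leaves), %d unassigned cells\n",
              nrow(x$nodes), sum(x$nodes$parent == "root"),
              sum(x$nodes$is_leaf), length(x$unassigned)))
  invisible(x)
}

#' Hierarchy nodes at a given depth
#'
#' Depth 1 is the first split (the top-level clusters under the virtual
#' root).
#'
#' @param h an `msc_hierarchy`.
#' @param depth depth to extract.
#' @return Character vector of node ids.
#' @export
hierarchy_level <- function(h, depth = 1L) {
  depth_of <- setNames(rep(NA_integer_, nrow(h$nodes)), h$nodes$id)
  depth_of[h$nodes$parent == "root"] <- 1L
  repeat {
    todo <- which(is.na(depth_of))
    if (!length(todo)) break
    progressed <- FALSE
    for (i in todo) {
      p <- h$nodes$parent[i]
      if (!is.na(depth_of[p])) {
        depth_of[i] <- depth_of[p] + 1L
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  h$nodes$id[which(depth_of == depth)]
}

#' All hierarchy nodes as an (overlapping) cluster collection
#'
#' Internal and leaf nodes together; the natural input to the overlap-aware
#' metrics.
#'
#' @param h an `msc_hierarchy`.
#' @param nodes optional subset of node ids.
#' @return A [cluster_collection()].
#' @export
hierarchy_clusters <- function(h, nodes = NULL) {
  sets <- h$cells
  if (!is.null(nodes)) sets <- sets[nodes]
  universe <- unique(c(unlist(h$cells, use.names = FALSE), h$unassigned))
  cluster_collection(sets, universe = universe)
}
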