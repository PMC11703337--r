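#' Default resolution grid
#'
#' Evenly spaced grid over `(0, 2]`, covering the neighbourhood of the
#' neutral resolution 1.
#'
#' @param step grid step (default 0.05).
#' @return Numeric vector `seq(step, 2, by = step)`.
#' @export
default_gamma_grid <- function(step = 0.05) {
  seq(step, 2, by = step)
}

as_igraph <- function(g) if (inherits(g, "cell_graph")) g$graph else g

#' Scan community-detection resolutions
#'
#' Runs Leiden clustering with the Reichardt-Bornholdt configuration-model
#' objective at every resolution of the grid and records the partition, the
#' cluster count and the intra-cluster link count K_in. Clustering is
#' unweighted: both K_in and the modularity objective are defined here through
#' link counts, and correlation weights may be negative.
#'
#' @param g a `cell_graph` or igraph object.
#' @param gammas increasing resolution grid in `(0, 2]`, at least 5 points.
#' @param seed RNG seed making the Leiden runs reproducible.
#' @param n_iterations Leiden iterations per resolution.
#' @return A `gamma_scan`: `table` (gamma, n_clusters, kin) plus the
#'   per-resolution memberships.
#' @export
scan_resolutions <- function(g, gammas = default_gamma_grid(), seed = 1L,
                             n_iterations = 10L) {
  ig <- as_igraph(g)
  if (igraph::vcount(ig) == 0) stop("empty graph")
  stopifnot(length(gammas) >= 5, all(gammas > 0), all(gammas <= 2),
            !is.unsorted(gammas))
  w1 <- rep(1, igraph::ecount(ig))
  memberships <- vector("list", length(gammas))
  kin <- integer(length(gammas))
  ncl <- integer(length(gammas))
  local_seed(seed, {
    for (t in seq_along(gammas)) {
      cl <- igraph::cluster_leiden(ig, objective_function = "modularity",
                                   weights = w1, resolution = gammas[t],
                                   n_iterations = n_iterations)
      mem <- setNames(igraph::membership(cl), igraph::V(ig)$name)
      memberships[[t]] <- mem
      kin[t] <- intra_cluster_links(ig, mem)
      ncl[t] <- length(unique(mem))
    }
  })
  structure(list(table = data.frame(gamma = gammas, n_clusters = ncl, kin = kin),
                 memberships = memberships),
            class = "gamma_scan")
}

#' @export
print.gamma_scan <- function(x, ...) {
  cat(sprintf("resolution scan: %d gammas in [%g, %g], K_in range [%d, %d]\n",
              nrow(x$table), min(x$table$gamma), max(x$table$gamma),
              min(x$table$kin), max(x$table$kin)))
  invisible(x)
}

#' Intra-cluster link count K_in
#'
#' Number of edges whose two endpoints share a cluster, each undirected edge
#' counted once.
#'
#' @param g a `cell_graph` or igraph object.
#' @param partition named membership vector covering all nodes of `g`.
#' @return Integer count.
#' @export
intra_cluster_links <- function(g, partition) {
  ig <- as_igraph(g)
  nodes <- igraph::V(ig)$name
  if (!all(nodes %in% names(partition))) {
    stop("partition is missing nodes: ",
         paste(head(setdiff(nodes, names(partition)), 5), collapse = ", "))
  }
  if (igraph::ecount(ig) == 0) return(0L)
  ends <- igraph::as_edgelist(ig, names = TRUE)
  sum(partition[ends[, 1]] == partition[ends[, 2]])
}

#' First stability breakpoint of the K_in profile
#'
#' Fits a piecewise-constant step model of K_in as a function of the
#' resolution by recursive binary partitioning (anova splitting): a split is
#' retained only when it reduces the total sum of squares by at least `cp`
#' times the root sum of squares, which prunes noise plateaus while keeping
#' genuine steps, is deterministic, and is invariant to affine rescaling of
#' K_in. The surviving split points cut the grid into regimes; a regime is
#' *stable* only if it spans at least `min_regime` grid points (K_in must be
#' stable across a range, and a single grid point has no range — a one-point
#' regime at the low end of the grid is a transient, not a solution). The
#' first stable regime is returned, bounded above by `gamma_prime`. When no
#' split survives the whole grid is the first regime.
#'
#' @param scan a `gamma_scan`.
#' @param cp complexity threshold for retaining a split (default 0.01).
#' @param min_regime smallest number of grid points a stable regime may span
#'   (default 2).
#' @return List with `gamma_prime` (upper boundary of the first stable
#'   regime), `regime_idx` (its grid indices) and `split_points`.
#' @export
detect_first_breakpoint <- function(scan, cp = 0.01, min_regime = 2L) {
  stopifnot(inherits(scan, "gamma_scan"))
  df <- scan$table
  if (nrow(df) < 5) stop("need >= 5 grid points")
  fit <- rpart::rpart(kin ~ gamma, data = df, method = "anova",
                      control = rpart::rpart.control(minsplit = 4,
                                                     minbucket = 1,
                                                     cp = cp, xval = 0,
                                                     maxcompete = 0,
                                                     maxsurrogate = 0))
  splits <- NULL
  if (!is.null(fit$splits) && nrow(fit$splits) > 0) {
    splits <- sort(unname(fit$splits[, "index"]))
  }
  if (is.null(splits)) {
    return(list(gamma_prime = max(df$gamma), regime_idx = seq_len(nrow(df)),
                split_points = numeric(0)))
  }
  segment <- findInterval(df$gamma, splits) + 1L # 1 = below first split
  regimes <- split(seq_len(nrow(df)), segment)
  stable <- which(vapply(regimes, length, 0L) >= min_regime)
  chosen <- if (length(stable)) stable[1] else 1L
  idx <- regimes[[chosen]]
  upper <- c(splits, max(df$gamma))[as.integer(names(regimes)[chosen])]
  list(gamma_prime = upper, regime_idx = idx, split_points = splits)
}

#' One adaptive split
#'
#' Scans the resolution grid, locates the first K_in breakpoint, and returns
#' the clustering at the median resolution of the first (coarse, low-gamma)
#' stable regime — the lower median for even-length regimes.
#'
#' @inheritParams scan_resolutions
#' @return List with `partition` (named membership), `gamma_f`, `n_clusters`,
#'   `no_split` (TRUE when the selected solution is all singletons or a single
#'   cluster) and the `scan`.
#' @export
adapt_split <- function(g, gammas = default_gamma_grid(), seed = 1L,
                        n_iterations = 10L) {
  scan <- scan_resolutions(g, gammas = gammas, seed = seed,
                           n_iterations = n_iterations)
  bp <- detect_first_breakpoint(scan)
  idx <- bp$regime_idx
  gf_idx <- idx[floor((length(idx) + 1) / 2)] # lower median
  partition <- scan$memberships[[gf_idx]]
  k <- length(unique(partition))
  list(partition = partition,
       gamma_f = scan$table$gamma[gf_idx],
       n_clusters = k,
       no_split = k <= 1 || k == length(partition),
       gamma_prime = bp$gamma_prime,
       scan = scan)
}
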