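#' Cluster collection
#'
#' Named sets of cell ids over a common universe; overlaps between clusters
#' are permitted (hierarchy nodes overlap by construction).
#'
#' @param clusters named list of nonempty character vectors.
#' @param universe all cell ids; defaults to the union of the clusters.
#' @return A `cluster_collection`.
#' @export
cluster_collection <- function(clusters, universe = NULL) {
  stopifnot(is.list(clusters), length(clusters) > 0)
  if (is.null(names(clusters))) {
    names(clusters) <- sprintf("C%d", seq_along(clusters))
  }
  clusters <- lapply(clusters, function(x) unique(as.character(x)))
  if (any(vapply(clusters, length, 0L) == 0)) stop("clusters must be nonempty")
  if (is.null(universe)) universe <- unique(unlist(clusters, use.names = FALSE))
  universe <- unique(as.character(universe))
  extra <- setdiff(unlist(clusters, use.names = FALSE), universe)
  if (length(extra)) stop("cluster members outside the universe: ",
                          paste(head(extra, 5), collapse = ", "))
  structure(list(clusters = clusters, universe = universe),
            class = "cluster_collection")
}

#' @export
print.cluster_collection <- function(x, ...) {
  cat(sprintf("cluster collection: %d clusters over %d cells\n",
              length(x$clusters), length(x$universe)))
  invisible(x)
}

as_collection <- function(x) {
  if (inherits(x, "cluster_collection")) return(x)
  if (inherits(x, "msc_hierarchy")) return(hierarchy_clusters(x))
  if (is.list(x)) return(cluster_collection(x))
  if (!is.null(names(x))) { # named membership vector
    return(cluster_collection(split(names(x), as.character(x))))
  }
  stop("cannot interpret input as a cluster collection")
}

# |A n B| matrix between two collections
overlap_matrix <- function(res, tru) {
  vapply(tru$clusters, function(tc) {
    vapply(res$clusters, function(rc) length(intersect(rc, tc)), 0L)
  }, integer(length(res$clusters)))
}

#' Inclusion rate (overlap-aware precision)
#'
#' Per result cluster, the best precision against any ground-truth cluster;
#' overall, the size-weighted mean over result clusters.
#'
#' @param result,truth `cluster_collection`s (or anything coercible: a
#'   hierarchy, a named membership vector, a list of sets).
#' @return List with `per_cluster` and `overall`.
#' @export
inclusion_rate <- function(result, truth) {
  res <- as_collection(result)
  tru <- as_collection(truth)
  ov <- overlap_matrix(res, tru)
  if (is.null(dim(ov))) ov <- matrix(ov, nrow = length(res$clusters))
  sizes <- vapply(res$clusters, length, 0L)
  per <- apply(ov / sizes, 1, max)
  names(per) <- names(res$clusters)
  list(per_cluster = per, overall = sum(per * sizes) / sum(sizes))
}

#' Coverage rate (overlap-aware recall)
#'
#' Per ground-truth cluster, the best recall against any result cluster;
#' overall, the size-weighted mean over truth clusters.
#'
#' @inheritParams inclusion_rate
#' @return List with `per_cluster` and `overall`.
#' @export
coverage_rate <- function(result, truth) {
  res <- as_collection(result)
  tru <- as_collection(truth)
  ov <- overlap_matrix(res, tru)
  if (is.null(dim(ov))) ov <- matrix(ov, nrow = length(res$clusters))
  tsizes <- vapply(tru$clusters, length, 0L)
  per <- apply(sweep(ov, 2, tsizes, "/"), 2, max)
  names(per) <- names(tru$clusters)
  list(per_cluster = per, overall = sum(per * tsizes) / sum(tsizes))
}

#' Detection accuracy (overlap-aware best Jaccard)
#'
#' Per ground-truth cluster, the best Jaccard index against any result
#' cluster; overall, the size-weighted mean over truth clusters.
#'
#' @inheritParams inclusion_rate
#' @return List with `per_cluster` and `overall`.
#' @export
detection_accuracy <- function(result, truth) {
  res <- as_collection(result)
  tru <- as_collection(truth)
  ov <- overlap_matrix(res, tru)
  if (is.null(dim(ov))) ov <- matrix(ov, nrow = length(res$clusters))
  rsz <- vapply(res$clusters, length, 0L)
  tsz <- vapply(tru$clusters, length, 0L)
  ji <- ov / (outer(rsz, tsz, "+") - ov)
  per <- apply(ji, 2, max)
  names(per) <- names(tru$clusters)
  list(per_cluster = per, overall = sum(per * tsz) / sum(tsz))
}

is_partition <- function(col) {
  members <- unlist(col$clusters, use.names = FALSE)
  !anyDuplicated(members) && setequal(members, col$universe)
}

#' Adjusted Rand index between two partitions
#'
#' Standard permutation-model adjusted Rand index; inputs must be proper
#' partitions (disjoint, covering the same universe).
#'
#' @param a,b partitions: named membership vectors, lists of disjoint sets or
#'   `cluster_collection`s.
#' @return The ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  ca <- as_collection(a)
  cb <- as_collection(b)
  if (!is_partition(ca) || !is_partition(cb)) {
    stop("ARI is defined for partitions only (disjoint, covering clusters)")
  }
  if (!setequal(ca$universe, cb$universe)) {
    stop("partitions must cover the same universe")
  }
  to_member <- function(col) {
    m <- rep(names(col$clusters), vapply(col$clusters, length, 0L))
    setNames(m, unlist(col$clusters, use.names = FALSE))
  }
  ma <- to_member(ca)
  mb <- to_member(cb)
  mclust::adjustedRandIndex(ma[ca$universe], mb[ca$universe])
}

#' Cluster-sample Fisher enrichment with condition labels
#'
#' For every (cluster, sample) pair, a one-sided Fisher's exact test of the
#' 2x2 table in-cluster/not x in-sample/not over all cells, adjusted by
#' Benjamini-Hochberg across all pairs jointly; a sample is enriched at
#' FDR < `fdr`, and a cluster is labelled for a condition when at least
#' `min_prop` of that condition's samples are enriched.
#'
#' @param clusters a `cluster_collection` (or coercible) of cell clusters.
#' @param cell_sample named character vector: sample of every cell.
#' @param sample_condition named character vector: condition of every sample.
#' @param fdr FDR threshold (default 0.05).
#' @param min_prop minimum proportion of enriched samples (default 0.5).
#' @return List with `table` (cluster, sample, condition, overlap, odds ratio,
#'   p, fdr, enriched) and `condition_labels` (cluster, condition, proportion,
#'   labelled).
#' @export
group_enrichment <- function(clusters, cell_sample, sample_condition,
                             fdr = 0.05, min_prop = 0.5) {
  col <- as_collection(clusters)
  cells <- col$universe
  missing_cells <- setdiff(cells, names(cell_sample))
  if (length(missing_cells)) {
    stop("cells without a sample assignment: ",
         paste(head(missing_cells, 5), collapse = ", "))
  }
  samp <- cell_sample[cells]
  samples <- sort(unique(samp))
  missing_s <- setdiff(samples, names(sample_condition))
  if (length(missing_s)) {
    stop("samples without a condition: ", paste(head(missing_s, 5), collapse = ", "))
  }
  n <- length(cells)
  rows <- list()
  for (cl in names(col$clusters)) {
    in_cl <- cells %in% col$clusters[[cl]]
    if (!any(in_cl)) next
    for (s in samples) {
      in_s <- samp == s
      a <- sum(in_cl & in_s)
      tab <- matrix(c(a, sum(in_cl & !in_s), sum(!in_cl & in_s),
                      sum(!in_cl & !in_s)), 2, 2)
      ft <- fisher.test(tab, alternative = "greater")
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, sample = s,
        condition = unname(sample_condition[s]),
        overlap = a, odds_ratio = unname(ft$estimate), p = ft$p.value)
    }
  }
  tab <- do.call(rbind, rows)
  tab$fdr <- p.adjust(tab$p, method = "BH")
  tab$enriched <- tab$fdr < fdr
  cond_of <- sample_condition[samples]
  labels <- list()
  for (cl in unique(tab$cluster)) {
    for (cond in unique(cond_of)) {
      cond_samples <- samples[cond_of == cond]
      sub <- tab[tab$cluster == cl & tab$sample %in% cond_samples, ]
      prop <- mean(sub$enriched)
      labels[[length(labels) + 1L]] <- data.frame(
        cluster = cl, condition = cond, proportion = prop,
        labelled = prop >= min_prop)
    }
  }
  list(table = tab, condition_labels = do.call(rbind, labels))
}
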