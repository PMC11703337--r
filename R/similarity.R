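#' Construct an expression matrix container
#'
#' Cells in rows, genes in columns. Real scRNA-seq input must be nonnegative;
#' set `allow_negative = TRUE` for continuous data such as the Gaussian
#' simulator output, where "expressed" still means strictly positive.
#'
#' @param values numeric matrix, cells x genes.
#' @param cell_ids,gene_ids unique identifiers; default dimnames.
#' @param feature_mask optional character vector of genes used for similarity.
#' @param allow_negative allow negative entries (continuous data).
#' @return An `msc_expr` object.
#' @export
expression_matrix <- function(values, cell_ids = rownames(values),
                              gene_ids = colnames(values),
                              feature_mask = NULL, allow_negative = FALSE) {
  values <- as.matrix(values)
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%04d", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_len(ncol(values)))
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (length(cell_ids) != nrow(values) || length(gene_ids) != ncol(values)) {
    stop("id lengths do not match matrix dimensions")
  }
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (!allow_negative && any(values < 0)) {
    stop("negative expression values found; counts/normalised expression must be nonnegative")
  }
  if (!is.null(feature_mask)) {
    missing_g <- setdiff(feature_mask, gene_ids)
    if (length(missing_g)) {
      stop("feature_mask contains unknown genes: ",
           paste(head(missing_g, 5), collapse = ", "))
    }
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, feature_mask = feature_mask),
            class = "msc_expr")
}

#' @export
print.msc_expr <- function(x, ...) {
  cat(sprintf("msc expression matrix: %d cells x %d genes%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$feature_mask)) ""
              else sprintf(" (%d masked features)", length(x$feature_mask))))
  invisible(x)
}

#' Convert a simulated dataset to an expression matrix
#'
#' Transposes the features x samples draw to cells x genes.
#'
#' @param sim an `msc_sim`.
#' @return An `msc_expr` (negative values allowed).
#' @export
as_expression_matrix <- function(sim) {
  stopifnot(inherits(sim, "msc_sim"))
  expression_matrix(t(sim$data), allow_negative = TRUE)
}

masked_values <- function(expr) {
  if (is.null(expr$feature_mask)) expr$values
  else expr$values[, expr$feature_mask, drop = FALSE]
}

#' Select variable features by variance
#'
#' Plumbing fallback when no externally derived variable-feature list is
#' supplied: retains the `q` genes with the largest variance across cells.
#'
#' @param expr an `msc_expr`.
#' @param q number of genes to keep (default 2000, capped at the gene count).
#' @return The `msc_expr` with `feature_mask` set.
#' @export
select_variable_features <- function(expr, q = 2000L) {
  stopifnot(inherits(expr, "msc_expr"))
  v <- apply(expr$values, 2, var)
  q <- min(as.integer(q), length(v))
  expr$feature_mask <- names(sort(v, decreasing = TRUE))[seq_len(q)]
  expr
}

new_similarity <- function(values, mode) {
  stopifnot(isSymmetric(unname(values)))
  structure(list(values = values, mode = mode,
                 higher_is_similar = TRUE),
            class = "msc_similarity")
}

#' @export
print.msc_similarity <- function(x, ...) {
  cat(sprintf("msc similarity matrix: %d cells, mode = %s\n",
              nrow(x$values), x$mode))
  invisible(x)
}

#' Pearson correlation similarity between cells
#'
#' Correlation across the masked features (all genes when no mask is set).
#'
#' @param expr an `msc_expr` with at least two (masked) features.
#' @return An `msc_similarity` with `mode = "correlation"`.
#' @export
pearson_similarity <- function(expr) {
  stopifnot(inherits(expr, "msc_expr"))
  x <- masked_values(expr)
  if (ncol(x) < 2) stop("need >= 2 features to compute correlations")
  cell_var <- apply(x, 1, var)
  if (any(cell_var == 0)) {
    stop("zero-variance cells over masked features: ",
         paste(head(rownames(x)[cell_var == 0], 10), collapse = ", "))
  }
  s <- cor(t(x))
  s <- (s + t(s)) / 2 # enforce exact symmetry against rounding
  new_similarity(s, "correlation")
}

#' Negated Euclidean distance similarity
#'
#' For reduced-coordinate input (e.g. principal components); stores the
#' negated distance so that every downstream step maximises similarity.
#'
#' @param coords numeric matrix, cells x components (>= 2 components).
#' @return An `msc_similarity` with `mode = "neg_euclidean"`.
#' @export
euclidean_similarity <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) < 2) stop("need >= 2 components")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (is.null(rownames(coords))) {
    rownames(coords) <- sprintf("cell_%04d", seq_len(nrow(coords)))
  }
  d <- as.matrix(dist(coords))
  new_similarity(-d, "neg_euclidean")
}

#' Jaccard index of expressed gene sets
#'
#' `|E_i intersect E_j| / |E_i union E_j|` where `E_c` is the set of genes
#' with strictly positive value in cell `c`; 0 when the union is empty.
#'
#' @param expr an `msc_expr`.
#' @param i,j cell ids or indices.
#' @return A number in `[0, 1]`.
#' @export
expressed_jaccard <- function(expr, i, j) {
  stopifnot(inherits(expr, "msc_expr"))
  ei <- expr$values[i, ] > 0
  ej <- expr$values[j, ] > 0
  u <- sum(ei | ej)
  if (u == 0) return(0)
  sum(ei & ej) / u
}

# vectorised expressed-set jaccard over an edge list (two id vectors)
expressed_jaccard_edges <- function(expr, from, to) {
  b <- expr$values > 0
  vapply(seq_along(from), function(k) {
    u <- sum(b[from[k], ] | b[to[k], ])
    if (u == 0) 0 else sum(b[from[k], ] & b[to[k], ]) / u
  }, numeric(1))
}
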