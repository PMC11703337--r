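# File formats: plain-text readers/writers for expression matrices,
# coordinates, similarity matrices, label tables, edge lists and hierarchies.

config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                     force = TRUE))
  h <- 7
  for (b in as.integer(charToRaw(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%x", h)
}

#' Read a dense expression TSV
#'
#' Genes in rows, cells in columns; first column holds gene ids, the header
#' holds cell ids. Values must be nonnegative unless `allow_negative` is set
#' (continuous data, e.g. simulator output).
#'
#' @param path file path.
#' @param allow_negative allow negative entries.
#' @return An `msc_expr` (cells x genes).
#' @export
read_expression_tsv <- function(path, allow_negative = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.delim(path, check.names = FALSE, comment.char = "#")
  gene_ids <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  expression_matrix(t(m), cell_ids = colnames(d)[-1], gene_ids = gene_ids,
                    allow_negative = allow_negative)
}

#' Read a 10x-style MatrixMarket triplet directory
#'
#' Expects `matrix.mtx`, `barcodes.tsv` and `features.tsv` (or `genes.tsv`)
#' in `dir`. Orientation (genes x cells vs cells x genes) is resolved from
#' the id counts.
#'
#' @param dir directory path.
#' @return An `msc_expr` (cells x genes).
#' @export
read_expression_mtx <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  bc <- file.path(dir, "barcodes.tsv")
  ft <- file.path(dir, "features.tsv")
  if (!file.exists(ft)) ft <- file.path(dir, "genes.tsv")
  for (f in c(mtx, bc, ft)) {
    if (!file.exists(f)) stop("missing file in MTX directory: ", f)
  }
  m <- as.matrix(Matrix::readMM(mtx))
  barcodes <- readLines(bc)
  feat <- read.delim(ft, header = FALSE)
  features <- make.unique(as.character(feat[[1]]))
  if (nrow(m) == length(features) && ncol(m) == length(barcodes)) {
    m <- t(m) # genes x cells on disk
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(features))) {
    stop("matrix dimensions match neither barcodes x features nor features x barcodes")
  }
  expression_matrix(m, cell_ids = barcodes, gene_ids = features)
}

#' Read reduced coordinates (cells x components)
#'
#' First column holds cell ids; remaining columns are numeric components.
#'
#' @param path file path.
#' @return A numeric matrix with cell-id rownames.
#' @export
read_coordinates_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.delim(path, check.names = FALSE, comment.char = "#")
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids)) stop("duplicate cell ids in ", path)
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m) || !all(is.finite(m))) stop("non-finite coordinates in ", path)
  rownames(m) <- ids
  m
}

#' Read a precomputed similarity matrix
#'
#' Square TSV with cell ids as header and first column; must be symmetric to
#' within 1e-8.
#'
#' @param path file path.
#' @param mode similarity mode to record.
#' @return An `msc_similarity`.
#' @export
read_similarity_tsv <- function(path, mode = "correlation") {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.delim(path, check.names = FALSE, comment.char = "#")
  ids <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  if (nrow(m) != ncol(m) || !identical(ids, colnames(m))) {
    stop("similarity matrix must be square with matching row/column ids")
  }
  if (max(abs(m - t(m))) > 1e-8) stop("similarity matrix is asymmetric beyond 1e-8")
  rownames(m) <- ids
  new_similarity((m + t(m)) / 2, mode)
}

#' Read a label table
#'
#' Two or more columns; the first is the cell id, `column` picks the label.
#'
#' @param path file path.
#' @param column label column name or index (default 2).
#' @return Named character vector of labels.
#' @export
read_labels_tsv <- function(path, column = 2L) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.delim(path, check.names = FALSE, comment.char = "#")
  setNames(as.character(d[[column]]), as.character(d[[1]]))
}

#' Write a simulated dataset
#'
#' Writes `PREFIX.data.tsv` (features x samples) and `PREFIX.labels.tsv`
#' (sample, inner_label, outer_label).
#'
#' @param sim an `msc_sim`.
#' @param prefix output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_sim_tsv <- function(sim, prefix) {
  stopifnot(inherits(sim, "msc_sim"))
  dpath <- paste0(prefix, ".data.tsv")
  lpath <- paste0(prefix, ".labels.tsv")
  dd <- data.frame(feature = rownames(sim$data), sim$data, check.names = FALSE)
  write.table(dd, dpath, sep = "\t", quote = FALSE, row.names = FALSE)
  ld <- data.frame(sample = colnames(sim$data),
                   inner_label = unname(sim$labels_inner),
                   outer_label = unname(sim$labels_outer))
  write.table(ld, lpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(dpath, lpath))
}

#' Write a cell graph as a weighted edge list
#'
#' Three tab-separated columns (cell_i, cell_j, weight) after a comment line
#' carrying the configuration hash.
#'
#' @param g a `cell_graph`.
#' @param path output path.
#' @param hash configuration hash recorded in the header comment.
#' @return Invisibly, `path`.
#' @export
write_edges_tsv <- function(g, path, hash = "none") {
  e <- graph_edges(g)
  con <- file(path, "w")
  writeLines(sprintf("# msclust edges stage=%s config=%s", g$stage, hash), con)
  writeLines("cell_i\tcell_j\tweight", con)
  if (nrow(e)) {
    writeLines(sprintf("%s\t%s\t%.10g", e$from, e$to, e$weight), con)
  }
  close(con)
  invisible(path)
}

#' Read a weighted edge list as a cell graph
#'
#' @param path edge-list TSV (cell_i, cell_j, weight).
#' @param stage,mode stage and similarity mode to record.
#' @return A `cell_graph`.
#' @export
read_edges_tsv <- function(path, stage = "final", mode = "correlation") {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.delim(path, comment.char = "#")
  names(d) <- c("from", "to", "weight")
  nodes <- sort(unique(c(d$from, d$to)))
  cell_graph(d, nodes = nodes, stage = stage, mode = mode)
}

#' Write a hierarchy as JSON plus a long membership table
#'
#' The JSON holds the node table (id, parent, size, gamma_f, v, lambda,
#' p_value, is_leaf), per-root alpha, unassigned cells and the configuration;
#' the TSV lists one (cell_id, node_id) row per node on each cell's
#' root-to-leaf path. No timestamps, so identical runs produce identical
#' bytes.
#'
#' @param h an `msc_hierarchy`.
#' @param json_path,membership_path output paths (NULL to skip either).
#' @return Invisibly, the written paths.
#' @export
write_hierarchy <- function(h, json_path = NULL, membership_path = NULL) {
  stopifnot(inherits(h, "msc_hierarchy"))
  hash <- config_hash(unclass(h$config))
  out <- character(0)
  if (!is.null(json_path)) {
    payload <- list(config_hash = hash,
                    config = unclass(h$config),
                    alpha = h$alpha,
                    nodes = h$nodes,
                    unassigned = h$unassigned,
                    cells = h$cells)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out <- c(out, json_path)
  }
  if (!is.null(membership_path)) {
    con <- file(membership_path, "w")
    writeLines(sprintf("# msclust membership config=%s", hash), con)
    writeLines("cell_id\tnode_id", con)
    writeLines(sprintf("%s\t%s", h$membership$cell_id, h$membership$node_id), con)
    close(con)
    out <- c(out, membership_path)
  }
  invisible(out)
}

#' Newick-like string of the hierarchy topology
#'
#' Node labels carry sizes as `id:size`; structure only, no branch lengths.
#'
#' @param h an `msc_hierarchy`.
#' @return A single string.
#' @export
hierarchy_newick <- function(h) {
  children_of <- split(h$nodes$id, h$nodes$parent)
  rec <- function(id) {
    lab <- sprintf("%s:%d", id, h$nodes$size[h$nodes$id == id])
    kids <- children_of[[id]]
    if (is.null(kids)) lab
    else sprintf("(%s)%s", paste(vapply(kids, rec, ""), collapse = ","), lab)
  }
  roots <- children_of[["root"]]
  sprintf("(%s)root;", paste(vapply(roots, rec, ""), collapse = ","))
}
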