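#' Define a simulation scenario
#'
#' Parameters of the multivariate Gaussian block-covariance generator. Samples
#' ("cells") fall into inner blocks with intra-block correlation `rho_in`;
#' in the two-layer scenarios inner blocks are adjoined into outer clusters
#' sharing a weaker correlation `rho_outer = rho_in - delta_rho`, and all
#' remaining pairs are uncorrelated. Every variable has unit variance and zero
#' mean, so covariance and correlation coincide. Independent Gaussian noise of
#' standard deviation `sigma` is added entrywise, which attenuates the
#' observable correlation to `rho / (1 + sigma^2)`.
#'
#' Scenario presets:
#' * `"I"`: single layer, irregular sizes — 12 blocks of 25, 6 of 50, 3 of
#'   100 (1050 cells); defaults `rho_in = 0.4`, `sigma = 1`.
#' * `"II"`: two layers, regular sizes — 21 inner blocks of 50, adjoined
#'   contiguously into 6 outer clusters of 4,4,4,3,3,3 blocks; defaults
#'   `rho_in = 0.25`, `delta_rho = 0.125`, `sigma = 0.2`.
#' * `"III"`: two layers, irregular sizes — same inner blocks as scenario I;
#'   each outer cluster merges 4 blocks of 25, 2 of 50 and 1 of 100
#'   (3 outer clusters of 300 cells); same correlation defaults as `"II"`.
#'
#' @param scenario `"I"`, `"II"` or `"III"`.
#' @param rho_in intra-block (inner-layer) correlation in `[0, 1)`.
#' @param delta_rho inner-minus-outer correlation difference (two-layer
#'   scenarios); `rho_outer = rho_in - delta_rho` must stay positive.
#' @param sigma additive noise standard deviation (>= 0).
#' @param n_features number of independent feature draws (rows), default 500.
#' @param seed integer seed for [simulate_dataset()].
#' @param inner_sizes,outer_grouping optional overrides of the preset block
#'   sizes and the mapping of inner blocks to outer clusters (integer vector,
#'   one outer id per inner block).
#' @return An object of class `msc_scenario`.
#' @export
scenario_spec <- function(scenario = c("I", "II", "III"),
                          rho_in = NULL, delta_rho = NULL, sigma = NULL,
                          n_features = 500L, seed = 1L,
                          inner_sizes = NULL, outer_grouping = NULL) {
  scenario <- match.arg(scenario)
  if (scenario == "I") {
    if (is.null(inner_sizes)) inner_sizes <- c(rep(25L, 12), rep(50L, 6), rep(100L, 3))
    if (is.null(rho_in)) rho_in <- 0.4
    if (is.null(sigma)) sigma <- 1
    delta_rho <- 0
    if (is.null(outer_grouping)) outer_grouping <- seq_along(inner_sizes)
  } else if (scenario == "II") {
    if (is.null(inner_sizes)) inner_sizes <- rep(50L, 21)
    if (is.null(rho_in)) rho_in <- 0.25
    if (is.null(delta_rho)) delta_rho <- 0.125
    if (is.null(sigma)) sigma <- 0.2
    if (is.null(outer_grouping)) {
      outer_grouping <- rep(seq_len(6), times = c(4L, 4L, 4L, 3L, 3L, 3L))
    }
  } else {
    if (is.null(inner_sizes)) inner_sizes <- c(rep(25L, 12), rep(50L, 6), rep(100L, 3))
    if (is.null(rho_in)) rho_in <- 0.25
    if (is.null(delta_rho)) delta_rho <- 0.125
    if (is.null(sigma)) sigma <- 0.2
    if (is.null(outer_grouping)) {
      # each outer cluster merges 4 size-25, 2 size-50 and 1 size-100 blocks
      outer_grouping <- c(rep(1:3, each = 4), rep(1:3, each = 2), 1:3)
    }
  }
  rho_outer <- if (scenario == "I") 0 else rho_in - delta_rho
  spec <- structure(list(
    scenario = scenario,
    inner_sizes = as.integer(inner_sizes),
    outer_grouping = as.integer(outer_grouping),
    rho_in = rho_in, rho_outer = rho_outer, rho_between = 0,
    sigma = sigma, n_features = as.integer(n_features),
    seed = as.integer(seed)
  ), class = "msc_scenario")
  validate_scenario(spec)
  spec
}

validate_scenario <- function(spec) {
  if (any(spec$inner_sizes < 2L)) stop("all inner block sizes must be >= 2")
  if (length(spec$outer_grouping) != length(spec$inner_sizes)) {
    stop("outer_grouping must assign every inner block to an outer cluster")
  }
  if (spec$rho_in < 0 || spec$rho_in >= 1) stop("rho_in must be in [0, 1)")
  if (spec$scenario != "I" && !(spec$rho_in > spec$rho_outer)) {
    stop("two-layer scenarios require rho_in > rho_outer")
  }
  if (spec$rho_outer < 0) stop("rho_outer must be >= 0 (is rho_in >= delta_rho?)")
  if (spec$sigma < 0) stop("sigma must be >= 0")
  if (spec$n_features < 2L) stop("n_features must be >= 2")
  invisible(spec)
}

#' @export
print.msc_scenario <- function(x, ...) {
  cat(sprintf(
    "msc scenario %s: %d cells in %d inner blocks / %d outer clusters\n",
    x$scenario, sum(x$inner_sizes), length(x$inner_sizes),
    length(unique(x$outer_grouping))))
  cat(sprintf("  rho_in = %g, rho_outer = %g, sigma = %g, n_features = %d, seed = %d\n",
              x$rho_in, x$rho_outer, x$sigma, x$n_features, x$seed))
  invisible(x)
}

# inner/outer block label per sample, in column order
scenario_labels <- function(spec) {
  inner <- rep(seq_along(spec$inner_sizes), times = spec$inner_sizes)
  outer <- spec$outer_grouping[inner]
  n <- sum(spec$inner_sizes)
  ids <- sprintf("cell_%04d", seq_len(n))
  list(ids = ids,
       inner = setNames(sprintf("I%02d", inner), ids),
       outer = setNames(sprintf("O%02d", outer), ids))
}

#' Build the block-structured correlation matrix of a scenario
#'
#' Unit diagonal; `rho_in` within inner blocks; `rho_outer` between samples
#' sharing an outer cluster but not an inner block; zero elsewhere.
#'
#' @param spec an `msc_scenario`.
#' @return A symmetric positive semi-definite correlation matrix.
#' @export
build_covariance <- function(spec) {
  validate_scenario(spec)
  lab <- scenario_labels(spec)
  inner_id <- rep(seq_along(spec$inner_sizes), times = spec$inner_sizes)
  outer_id <- spec$outer_grouping[inner_id]
  same_inner <- outer(inner_id, inner_id, "==")
  same_outer <- outer(outer_id, outer_id, "==")
  sigma_m <- matrix(0, length(inner_id), length(inner_id))
  sigma_m[same_outer] <- spec$rho_outer
  sigma_m[same_inner] <- spec$rho_in
  diag(sigma_m) <- 1
  dimnames(sigma_m) <- list(lab$ids, lab$ids)
  # verify positive semi-definiteness by Cholesky with a tiny jitter
  ok <- tryCatch({
    chol(sigma_m + diag(1e-10, nrow(sigma_m)))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    stop(sprintf(
      "correlation structure is not positive semi-definite (rho_in = %g, rho_outer = %g, sizes %s)",
      spec$rho_in, spec$rho_outer, paste(spec$inner_sizes, collapse = ",")))
  }
  sigma_m
}

#' Draw a simulated dataset from a scenario
#'
#' Each of the `n_features` rows is an independent draw from
#' `N(0, Sigma)` over the samples, plus independent `N(0, sigma^2)` noise per
#' entry. Deterministic given `spec$seed`.
#'
#' @param spec an `msc_scenario`.
#' @return An `msc_sim` with `data` (features x samples), `labels_inner`,
#'   `labels_outer` (named by cell id) and the `spec`.
#' @export
simulate_dataset <- function(spec) {
  validate_scenario(spec)
  sigma_m <- build_covariance(spec)
  lab <- scenario_labels(spec)
  n <- ncol(sigma_m)
  # chol() may need jitter on exactly singular block structures (rho -> 1)
  cf <- tryCatch(chol(sigma_m),
                 error = function(e) chol(sigma_m + diag(1e-10, n)))
  dat <- local_seed(derive_seed(spec$seed, "simulate"), {
    z <- matrix(rnorm(spec$n_features * n), spec$n_features, n)
    x <- z %*% cf # rows are independent N(0, Sigma) draws
    if (spec$sigma > 0) {
      x <- x + matrix(rnorm(spec$n_features * n, sd = spec$sigma),
                      spec$n_features, n)
    }
    x
  })
  dimnames(dat) <- list(sprintf("f%04d", seq_len(spec$n_features)), lab$ids)
  structure(list(data = dat,
                 labels_inner = lab$inner,
                 labels_outer = lab$outer,
                 spec = spec),
            class = "msc_sim")
}

#' @export
print.msc_sim <- function(x, ...) {
  cat(sprintf("msc simulated dataset: %d features x %d cells (scenario %s)\n",
              nrow(x$data), ncol(x$data), x$spec$scenario))
  invisible(x)
}

#' Ground-truth clusters of a simulated dataset
#'
#' @param sim an `msc_sim`.
#' @param layer `"inner"` or `"outer"`.
#' @return A [cluster_collection()] of the ground-truth blocks.
#' @export
truth_clusters <- function(sim, layer = c("inner", "outer")) {
  layer <- match.arg(layer)
  lab <- if (layer == "inner") sim$labels_inner else sim$labels_outer
  cluster_collection(split(names(lab), lab), universe = names(lab))
}
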