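#' @useDynLib discriminability, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# metric registry: names -> function(features) returning an N x N matrix
.metrics <- new.env(parent = emptyenv())
.metrics$euclidean <- function(x) as.matrix(stats::dist(x, method = "euclidean"))
.metrics$manhattan <- function(x) as.matrix(stats::dist(x, method = "manhattan"))

#' Register a dissimilarity metric
#'
#' Any dissimilarity can drive the discriminability analysis; only the
#' Euclidean distance is built in as the default (with Manhattan as a second
#' registered option). A metric takes the feature matrix and returns a full
#' symmetric matrix of non-negative dissimilarities with a zero diagonal.
#'
#' @param name metric name used in [compute_distances()].
#' @param fn function of one argument (the \eqn{N \times d} feature matrix)
#'   returning an \eqn{N \times N} matrix.
#' @export
register_metric <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .metrics)
  invisible(name)
}

#' Compute a pairwise distance matrix
#'
#' Step one of the discriminability computation: the distance between all
#' pairs of measurements. For \eqn{n} items with two measurements each this
#' is the \eqn{2n \times 2n} matrix whose within-item entries are compared
#' against its across-item entries.
#'
#' @param ms a [measurement_set()] or numeric matrix.
#' @param metric name of a registered metric (default `"euclidean"`).
#' @param ids item labels, required when `ms` is a bare matrix.
#' @return An object of class `"distance_matrix"`: list with `values`
#'   (\eqn{N \times N} symmetric, zero diagonal, non-negative) and `ids`,
#'   aligned with the row order of `ms`.
#' @export
compute_distances <- function(ms, metric = "euclidean", ids = NULL) {
  if (inherits(ms, "measurement_set")) {
    x <- ms$features
    ids <- ms$ids
  } else {
    x <- as.matrix(ms)
    if (is.null(ids)) stop("'ids' is required when 'ms' is not a measurement_set")
    ids <- as.character(ids)
  }
  if (!all(is.finite(x))) stop("non-finite feature values")
  if (!exists(metric, envir = .metrics, inherits = FALSE)) {
    stop("unknown metric: '", metric, "' (registered: ",
         paste(ls(.metrics), collapse = ", "), ")")
  }
  D <- get(metric, envir = .metrics)(x)
  as_distance_matrix(D, ids)
}

#' Construct a distance matrix object from precomputed values
#'
#' Validates symmetry, non-negativity and a zero diagonal, so that
#' downstream rank comparisons are well defined.
#'
#' @param values \eqn{N \times N} numeric matrix.
#' @param ids length-\eqn{N} item labels in the row order of `values`.
#' @export
as_distance_matrix <- function(values, ids) {
  values <- as.matrix(values)
  ids <- as.character(ids)
  if (nrow(values) != ncol(values) || nrow(values) != length(ids)) {
    stop("'values' must be square with one row per id")
  }
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-10))) {
    stop("distance matrix must be symmetric")
  }
  values <- (values + t(values)) / 2
  if (any(values < 0)) stop("distance matrix must be non-negative")
  diag(values) <- 0
  structure(list(values = values, ids = ids), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("Distance matrix: %d measurements, %d items\n",
              nrow(x$values), length(unique(x$ids))))
  invisible(x)
}

#' Edge-weight transforms
#'
#' Connectome-style weight rescalings compared in the strategy-selection
#' experiments: `raw` leaves weights untouched; `rank` keeps exact zeros at
#' zero and replaces non-zero weights by their ascending rank (ties get the
#' average rank), making the result invariant to any strictly increasing
#' transform of the non-zero weights; `log` takes the natural log, with
#' exact zeros mapped to `log(eps)` where `eps` is the smallest non-zero
#' weight times 1e-3 (a monotone completion of the log at zero).
#'
#' @param values non-negative numeric vector.
#' @param mode `"raw"`, `"rank"`, or `"log"`.
#' @return numeric vector of the same length.
#' @examples
#' transform_weights(c(5, 0, 2, 9), "rank") # 2 0 1 3
#' @export
transform_weights <- function(values, mode = c("raw", "rank", "log")) {
  mode <- match.arg(mode)
  if (mode == "raw") return(values)
  if (any(values < 0)) stop("negative weights are not allowed under '", mode, "'")
  if (mode == "rank") {
    out <- numeric(length(values))
    nz <- values > 0
    out[nz] <- rank(values[nz], ties.method = "average")
    return(out)
  }
  # log
  nz <- values > 0
  if (!any(nz)) stop("cannot log-transform an all-zero weight vector")
  eps <- min(values[nz]) * 1e-3
  out <- values
  out[!nz] <- eps
  log(out)
}
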