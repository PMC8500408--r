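#' Inter-item discriminability
#'
#' `discr()` estimates the discriminability of a set of repeated multivariate
#' measurements: the fraction of (within-item pair, across-item measurement)
#' comparisons in which the across-item distance is *not* smaller than the
#' within-item distance. A value of 1 means every measurement is closer to
#' its item-mates than to any other item's measurements; exchangeable data
#' (no item-specific information) have discriminability 0.5 in expectation.
#'
#' For item \eqn{i} with \eqn{s_i \ge 2} measurements, every ordered
#' within-item pair \eqn{(j, j')} is compared against every measurement
#' \eqn{k} of a different item: a violation occurs when
#' \eqn{D(j,k) < D(j,j')}, and an exact tie counts one half. The statistic
#' is the mean of the per-measurement discriminabilities over all
#' measurements belonging to items with replicates. In the balanced
#' \eqn{s_i \equiv 2}, tie-free case this reduces exactly to
#' \deqn{\mathrm{Discr} = 1 - \frac{f}{N(N-1) - g},}
#' with \eqn{f} the number of violations, \eqn{g = 2n} the number of
#' within-item pairs and \eqn{N = \sum_i s_i}. Because only ranks of
#' distances enter, the statistic is invariant to strictly increasing
#' transforms of the distances, hence to monotone rescalings, rotations, and
#' translations of Euclidean data.
#'
#' Items with a single measurement carry no within-item pair; they are
#' dropped from the computation with a warning and reported in the fitted
#' object.
#'
#' @param x a [measurement_set()], a numeric feature matrix, a
#'   [stats::dist] object, or a `"distance_matrix"`.
#' @param ids item labels, required for matrix or `dist` input.
#' @param metric registered metric name used when distances must be computed
#'   (default Euclidean).
#' @param ... passed between methods.
#' @return An object of class `"discr"` with elements `statistic` (the
#'   estimate in \[0, 1\]), `f` (tie-weighted violation count), `g` (number
#'   of ordered within-item pairs), `n_comparisons` (total comparisons),
#'   `per_measurement` (length-\eqn{N}, `NA` for singleton items), `ids`,
#'   and `excluded` (singleton item labels).
#' @examples
#' ms <- sim_1d("discriminable")
#' fit <- discr(ms)
#' fit
#' summary(fit)
#' @export
discr <- function(x, ...) UseMethod("discr")

#' @rdname discr
#' @export
discr.measurement_set <- function(x, metric = "euclidean", ...) {
  out <- discr(compute_distances(x, metric = metric), ...)
  out$call <- match.call()
  out
}

#' @rdname discr
#' @export
discr.matrix <- function(x, ids, metric = "euclidean", ...) {
  out <- discr(compute_distances(x, metric = metric, ids = ids), ...)
  out$call <- match.call()
  out
}

#' @rdname discr
#' @export
discr.dist <- function(x, ids, ...) {
  out <- discr(as_distance_matrix(as.matrix(x), ids), ...)
  out$call <- match.call()
  out
}

#' @rdname discr
#' @export
discr.distance_matrix <- function(x, ...) {
  res <- discr_fit(x$values, x$ids)
  res$call <- match.call()
  res
}

# shared fitting path; D a plain matrix, ids character
discr_fit <- function(D, ids, warn_singletons = TRUE) {
  si <- table(ids)
  if (sum(si >= 2L) < 2L) {
    stop("discriminability needs at least 2 items with >= 2 measurements")
  }
  if (warn_singletons && any(si < 2L)) {
    warning(sprintf("%d item(s) with a single measurement excluded from Discr",
                    sum(si < 2L)))
  }
  item <- as.integer(factor(ids)) - 1L
  cnt <- .discr_counts(D, item)
  per <- cnt$per_measurement
  g <- sum(si * (si - 1))
  structure(
    list(statistic = mean(per, na.rm = TRUE),
         f = cnt$f,
         g = as.numeric(g),
         n_comparisons = cnt$n_comparisons,
         per_measurement = per,
         ids = ids,
         excluded = names(si)[si < 2L],
         call = NULL),
    class = "discr")
}

#' Per-measurement discriminabilities
#'
#' Entry \eqn{j} is the fraction of comparisons anchored at measurement
#' \eqn{j} that are not violated; the mean over measurements of items with
#' replicates equals the Discr statistic. Measurements of singleton items
#' are `NA`.
#'
#' @param D a `"distance_matrix"` (or a [measurement_set()], in which case
#'   Euclidean distances are computed first).
#' @return numeric vector of length \eqn{N}.
#' @export
discr_per_measurement <- function(D) {
  discr(D)$per_measurement
}

#' @export
print.discr <- function(x, digits = 4, ...) {
  cat("Inter-item discriminability\n")
  cat(sprintf("  Discr = %.*f  (N = %d measurements, %d items)\n",
              digits, x$statistic, length(x$per_measurement),
              length(unique(x$ids))))
  if (length(x$excluded)) {
    cat(sprintf("  excluded singleton items: %s\n", paste(x$excluded, collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.discr <- function(object, ...) {
  per <- object$per_measurement
  by_item <- tapply(per, object$ids, mean)
  out <- list(statistic = object$statistic,
              f = object$f, g = object$g,
              n_comparisons = object$n_comparisons,
              per_measurement = stats::quantile(per, na.rm = TRUE),
              worst_items = sort(by_item)[seq_len(min(5L, sum(!is.na(by_item))))])
  class(out) <- "summary.discr"
  out
}

#' @export
print.summary.discr <- function(x, digits = 4, ...) {
  cat(sprintf("Discr = %.*f\n", digits, x$statistic))
  cat(sprintf("violations f = %.1f over %.0f comparisons (g = %.0f within-item pairs)\n",
              x$f, x$n_comparisons, x$g))
  cat("per-measurement discriminability quantiles:\n")
  print(round(x$per_measurement, digits))
  cat("least discriminable items (mean per-measurement value):\n")
  print(round(x$worst_items, digits))
  invisible(x)
}

#' @export
coef.discr <- function(object, ...) c(discr = object$statistic)

#' @export
plot.discr <- function(x, ...) {
  per <- x$per_measurement
  ord <- order(x$ids)
  graphics::plot(seq_along(per), per[ord], ylim = c(0, 1),
                 xlab = "measurement (grouped by item)",
                 ylab = "per-measurement discriminability",
                 pch = 19, col = as.integer(factor(x$ids[ord])), ...)
  graphics::abline(h = x$statistic, lty = 2)
  invisible(x)
}
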