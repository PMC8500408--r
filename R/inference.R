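# ---- statistic evaluation layer -------------------------------------------
#
# Permutation tests re-evaluate a statistic hundreds of times on relabelled
# or re-partitioned data. All supported statistics can be computed from
# matrices that do not change under relabelling (distances, squared
# distances, a kernel matrix with its bandwidth fixed up front, PCA scores
# recomputed per subset), so a context of precomputed matrices is built once
# and each permutation is a cheap re-evaluation.

stat_names <- function() c("discr", "icc", "picc", "i2c2", "fingerprint", "kernel")

build_context <- function(x, stat) {
  stat <- match.arg(stat, stat_names())
  if (inherits(x, "measurement_set")) {
    X <- x$features
    D <- as.matrix(stats::dist(X))
    ids <- x$ids
    sessions <- x$sessions
  } else if (inherits(x, "distance_matrix")) {
    if (stat %in% c("icc", "picc", "i2c2")) {
      stop("'", stat, "' needs feature input, not a distance matrix")
    }
    X <- NULL
    D <- x$values
    ids <- x$ids
    sessions <- NULL
  } else {
    stop("'x' must be a measurement_set or distance_matrix")
  }
  ctx <- list(X = X, D = D, ids = ids, sessions = sessions, stat = stat)
  if (stat == "i2c2") ctx$D2 <- D^2
  if (stat == "kernel") {
    sigma <- median_bandwidth(D)
    ctx$K <- exp(-D^2 / (2 * sigma^2))
  }
  if (is.null(sessions) && stat == "fingerprint") {
    ctx$sessions <- default_sessions(ids)
  }
  ctx
}

eval_stat <- function(ctx, ids, rows = NULL) {
  if (is.null(rows)) rows <- seq_along(ids)
  switch(ctx$stat,
    discr = .discr_mean(ctx$D, as.integer(factor(ids)) - 1L, as.integer(rows - 1L)),
    icc = {
      if (ncol(ctx$X) != 1L) stop("ICC is univariate; use picc for multivariate data")
      icc_value(ctx$X[rows, 1L], ids)$value
    },
    picc = icc_value(picc_scores(ctx$X[rows, , drop = FALSE])$scores, ids)$value,
    i2c2 = i2c2_value(ctx$X[rows, , drop = FALSE],
                      ctx$D2[rows, rows, drop = FALSE], ids)$value,
    fingerprint = fingerprint_value(ctx$D[rows, rows, drop = FALSE], ids,
                                    ctx$sessions[rows])$value,
    kernel = kernel_value(ctx$K[rows, rows, drop = FALSE], ids))
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

new_test_result <- function(observed, null_sample, n_perm, seed, stat, type) {
  structure(
    list(observed = observed,
         null_sample = null_sample,
         p_value = (1 + sum(null_sample >= observed)) / (1 + n_perm),
         n_perm = n_perm,
         seed = seed,
         alternative = "greater",
         stat = stat,
         type = type),
    class = "discr_test")
}

#' One-sample replicability test
#'
#' Tests \eqn{H_0: R = R_0} against \eqn{H_A: R > R_0}, where \eqn{R} is the
#' replicability of the observed data and \eqn{R_0} that of equally sized
#' data carrying no item-specific information. The null distribution is
#' obtained by uniformly permuting the item labels over measurements (which
#' preserves the multiset of replicate counts); the p-value uses the add-one
#' formula \eqn{(1 + \#\{R^{(b)} \ge R\}) / (1 + B)}, so it is never zero
#' and the test is valid at any number of permutations.
#'
#' @param x a [measurement_set()], or a `"distance_matrix"` for
#'   distance-based statistics (`discr`, `fingerprint`, `kernel`).
#' @param stat statistic to test: one of `"discr"`, `"icc"`, `"picc"`,
#'   `"i2c2"`, `"fingerprint"`, `"kernel"`.
#' @param n_perm number of label permutations (default 500).
#' @param seed integer seed; permutations are pre-drawn from it so results
#'   are reproducible and independent of evaluation order.
#' @return An object of class `"discr_test"`: `observed`, `null_sample`
#'   (length `n_perm`), `p_value`, `n_perm`, `seed`, `alternative`.
#' @examples
#' ms <- sim_1d("discriminable")
#' test_one_sample(ms, n_perm = 100, seed = 1)
#' @export
test_one_sample <- function(x, stat = "discr", n_perm = 500L, seed = 1L) {
  stopifnot(n_perm >= 1L)
  ctx <- build_context(x, stat)
  observed <- eval_stat(ctx, ctx$ids)
  perms <- with_seed(seed, lapply(seq_len(n_perm), function(b) sample(ctx$ids)))
  null_sample <- vapply(perms, function(p) eval_stat(ctx, p), numeric(1))
  new_test_result(observed, null_sample, n_perm, seed, ctx$stat, "one_sample")
}

#' Two-sample replicability comparison test
#'
#' Tests \eqn{H_0: R^{(1)} = R^{(2)}} against \eqn{H_A: R^{(1)} > R^{(2)}}
#' for two measurement strategies applied to the same items (paired, with
#' identical per-item replicate counts). The observed statistic is
#' \eqn{R^{(1)} - R^{(2)}}. Null draws swap, independently per item with
#' probability 1/2, that item's whole block of measurements between the two
#' strategies and recompute the difference; this preserves within-strategy
#' dependence while enforcing exchangeability of the strategy labels. The
#' features of both sets are stacked and one distance (and, if needed,
#' kernel) matrix is computed up front, so each permutation is a row-subset
#' evaluation.
#'
#' @param ms1,ms2 [measurement_set()] objects with identical item label
#'   vectors; `ms1` is the strategy hypothesized to be more replicable.
#' @inheritParams test_one_sample
#' @return a `"discr_test"` whose `observed` is \eqn{R^{(1)} - R^{(2)}}.
#' @export
test_two_sample <- function(ms1, ms2, stat = "discr", n_perm = 500L, seed = 1L) {
  stopifnot(inherits(ms1, "measurement_set"), inherits(ms2, "measurement_set"),
            n_perm >= 1L)
  if (!identical(ms1$ids, ms2$ids)) {
    stop("the two strategies must measure the same items with the same replicate counts, in the same row order")
  }
  if (ncol(ms1$features) != ncol(ms2$features)) {
    stop("the two strategies must have the same feature dimension")
  }
  N <- nrow(ms1$features)
  stacked <- measurement_set(rbind(ms1$features, ms2$features),
                             ids = c(ms1$ids, ms2$ids),
                             sessions = if (!is.null(ms1$sessions)) c(ms1$sessions, ms2$sessions))
  ctx <- build_context(stacked, stat)
  blocks <- split(seq_len(N), ms1$ids)
  rows1 <- seq_len(N)
  # each side keeps the original measurement positions, so that a swap of
  # identical data reproduces the observed statistic bit for bit
  diff_stat <- function(sel1, sel2) {
    eval_stat(ctx, ctx$ids[sel1], rows = sel1) -
      eval_stat(ctx, ctx$ids[sel2], rows = sel2)
  }
  observed <- diff_stat(rows1, rows1 + N)
  flips <- with_seed(seed, matrix(stats::runif(n_perm * length(blocks)) < 0.5,
                                  nrow = n_perm))
  null_sample <- vapply(seq_len(n_perm), function(b) {
    sel1 <- rows1
    sel2 <- rows1 + N
    for (i in seq_along(blocks)) {
      if (flips[b, i]) {
        sel1[blocks[[i]]] <- blocks[[i]] + N
        sel2[blocks[[i]]] <- blocks[[i]]
      }
    }
    diff_stat(sel1, sel2)
  }, numeric(1))
  new_test_result(observed, null_sample, n_perm, seed, ctx$stat, "two_sample")
}

#' @export
print.discr_test <- function(x, digits = 4, ...) {
  lab <- if (x$type == "one_sample") {
    "One-sample replicability test (H0: no item-specific information)"
  } else {
    "Two-sample replicability comparison (H0: R(1) = R(2))"
  }
  cat(lab, "\n")
  cat(sprintf("  statistic: %s%s = %.*f\n", x$stat,
              if (x$type == "two_sample") " difference" else "", digits, x$observed))
  cat(sprintf("  p-value = %.*g  (%d permutations, alternative: %s, seed %d)\n",
              digits, x$p_value, x$n_perm, x$alternative, x$seed))
  invisible(x)
}
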