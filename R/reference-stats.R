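#' @name reference-stats
#' @title Comparator replicability statistics
#'
#' @description
#' The statistics Discr is benchmarked against: the one-way random-effects
#' intraclass correlation (ICC), ICC on the top principal component (PICC),
#' the image intraclass correlation (I2C2, trace-ratio form), the
#' fingerprint index, the k-sample kernel statistic (unbiased MMD^2 averaged
#' over item pairs), and the unbiased distance correlation used as a
#' downstream effect size. Each returns a `"replicability_stat"` object with
#' the statistic name, its value, and estimator details.
NULL

new_stat <- function(name, value, details = list()) {
  structure(list(name = name, value = value, details = details),
            class = "replicability_stat")
}

#' @export
print.replicability_stat <- function(x, digits = 4, ...) {
  cat(sprintf("%s = %.*f\n", x$name, digits, x$value))
  invisible(x)
}

#' Intraclass correlation coefficient (one-way random effects)
#'
#' \eqn{ICC = (MS_B - MS_W) / (MS_B + (k_0 - 1) MS_W)} from a one-way ANOVA
#' with items as the random factor, where \eqn{k_0} is the standard
#' unbalanced-design correction to the mean replicate count,
#' \eqn{k_0 = (N - \sum s_i^2/N)/(n-1)}. May be negative when within-item
#' scatter exceeds between-item scatter.
#'
#' @param x numeric vector (one univariate measurement per row).
#' @param ids item labels.
#' @return a `"replicability_stat"` (details: `msb`, `msw`, `k0`).
#' @export
icc <- function(x, ids) {
  v <- icc_value(as.numeric(x), as.character(ids))
  new_stat("icc", v$value, v[c("msb", "msw", "k0")])
}

icc_value <- function(x, ids) {
  f <- factor(ids)
  si <- as.vector(table(f))
  if (sum(si >= 2L) < 2L) stop("ICC needs at least 2 items with replicates")
  n <- nlevels(f)
  N <- length(x)
  m <- tapply(x, f, mean)
  g <- mean(x)
  msb <- sum(si * (m - g)^2) / (n - 1)
  msw <- sum((x - m[f])^2) / (N - n)
  if (msb == 0 && msw == 0) stop("ICC undefined: input is constant")
  k0 <- (N - sum(si^2) / N) / (n - 1)
  list(value = (msb - msw) / (msb + (k0 - 1) * msw), msb = msb, msw = msw, k0 = k0)
}

#' ICC of the top principal component (PICC)
#'
#' Projects the (column-centered, unscaled) features onto their first
#' principal component and applies [icc()] to the scores. For univariate
#' data this is identical to `icc`.
#'
#' @param ms a [measurement_set()].
#' @return a `"replicability_stat"` (details include the PC1 loading).
#' @export
picc <- function(ms) {
  s <- picc_scores(ms$features)
  v <- icc_value(s$scores, ms$ids)
  new_stat("picc", v$value, c(v[c("msb", "msw", "k0")], list(loading = s$loading)))
}

picc_scores <- function(X) {
  X <- as.matrix(X)
  if (all(apply(X, 2, stats::sd) == 0)) stop("PICC undefined: feature matrix has rank zero")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  list(scores = p$x[, 1L], loading = p$rotation[, 1L])
}

#' Image intraclass correlation (I2C2), trace-ratio moment estimator
#'
#' Under the additive two-level model \eqn{W_{ij} = \mu + X_i + U_{ij}},
#' estimates \eqn{tr(\Sigma_X) / (tr(\Sigma_X) + tr(\Sigma_U))}.
#' \eqn{tr(\hat\Sigma_U)} is the mean of \eqn{\tfrac12\|W_{ij}-W_{ij'}\|^2}
#' over within-item pairs; \eqn{tr(\hat\Sigma_X)} is the total trace minus
#' that, floored at 0; the ratio is truncated to \[0, 1\].
#'
#' @param ms a [measurement_set()].
#' @return a `"replicability_stat"` (details: `tr_item`, `tr_noise`).
#' @export
i2c2 <- function(ms) {
  D2 <- as.matrix(stats::dist(ms$features))^2
  v <- i2c2_value(ms$features, D2, ms$ids)
  new_stat("i2c2", v$value, v[c("tr_item", "tr_noise")])
}

i2c2_value <- function(X, D2, ids) {
  f <- factor(ids)
  within <- outer(f, f, "==") & upper.tri(D2)
  if (!any(within)) stop("I2C2 needs within-item pairs")
  tr_noise <- mean(D2[within]) / 2
  tr_total <- sum(apply(X, 2, stats::var))
  tr_item <- max(0, tr_total - tr_noise)
  denom <- tr_item + tr_noise
  value <- if (denom == 0) 0 else min(1, max(0, tr_item / denom))
  list(value = value, tr_item = tr_item, tr_noise = tr_noise)
}

#' Fingerprint index
#'
#' The fraction of items whose session-1 measurement has its nearest
#' neighbour, among all session-2 measurements, belonging to the same item
#' (matching in the identification sense), averaged over the two directions
#' 1→2 and 2→1. Distance ties are broken toward a mismatch. When more than
#' two sessions exist only the first two are used; without session labels,
#' each item's first two measurements (in row order) act as sessions 1 and 2.
#'
#' @param ms a [measurement_set()] in which items have measurements in at
#'   least two sessions.
#' @return a `"replicability_stat"` (details: per-direction match rates).
#' @export
fingerprint_index <- function(ms) {
  D <- as.matrix(stats::dist(ms$features))
  v <- fingerprint_value(D, ms$ids, ms$sessions)
  new_stat("fingerprint", v$value, v[c("match_12", "match_21", "n_items")])
}

default_sessions <- function(ids) {
  stats::ave(seq_along(ids), ids, FUN = seq_along)
}

fingerprint_value <- function(D, ids, sessions = NULL) {
  if (is.null(sessions)) sessions <- default_sessions(ids)
  s1 <- which(sessions == 1L)
  s2 <- which(sessions == 2L)
  keep <- intersect(ids[s1], ids[s2])
  if (length(keep) < 2L) stop("fingerprint needs >= 2 items with two sessions")
  s1 <- s1[ids[s1] %in% keep]
  s2 <- s2[ids[s2] %in% keep]
  one_dir <- function(from, to) {
    hits <- vapply(from, function(j) {
      d <- D[j, to]
      winners <- to[d == min(d)]
      all(ids[winners] == ids[j]) # any tying other-item neighbour -> mismatch
    }, logical(1))
    mean(hits)
  }
  m12 <- one_dir(s1, s2)
  m21 <- one_dir(s2, s1)
  list(value = (m12 + m21) / 2, match_12 = m12, match_21 = m21,
       n_items = length(keep))
}

#' Kernel k-sample statistic
#'
#' Treats items as groups and averages the unbiased squared maximum mean
#' discrepancy (MMD^2) over all pairs of items with replicates, using a
#' Gaussian kernel whose bandwidth is the median of the pooled pairwise
#' distances (fixed before any permutation). The unbiased estimator can be
#' negative on null data; the reported value is floored at 0 and the raw
#' average is kept in the details.
#'
#' @param ms a [measurement_set()].
#' @return a `"replicability_stat"` (details: `raw`, `bandwidth`).
#' @export
kernel_stat <- function(ms) {
  D <- as.matrix(stats::dist(ms$features))
  sigma <- median_bandwidth(D)
  K <- exp(-D^2 / (2 * sigma^2))
  v <- kernel_value(K, ms$ids)
  new_stat("kernel", max(0, v), list(raw = v, bandwidth = sigma))
}

median_bandwidth <- function(D) {
  d <- D[upper.tri(D)]
  sigma <- stats::median(d)
  if (sigma == 0) sigma <- 1 # degenerate: all points identical
  sigma
}

kernel_value <- function(K, ids) {
  f <- factor(ids)
  grp <- split(seq_along(ids), f)
  grp <- grp[vapply(grp, length, integer(1)) >= 2L]
  if (length(grp) < 2L) stop("kernel statistic needs >= 2 items with replicates")
  mmd_pair <- function(a, b) {
    Kaa <- K[a, a]; Kbb <- K[b, b]; Kab <- K[a, b, drop = FALSE]
    na <- length(a); nb <- length(b)
    (sum(Kaa) - sum(diag(Kaa))) / (na * (na - 1)) +
      (sum(Kbb) - sum(diag(Kbb))) / (nb * (nb - 1)) -
      2 * mean(Kab)
  }
  tot <- 0; np <- 0
  for (i in seq_along(grp)[-length(grp)]) {
    for (j in seq((i + 1), length(grp))) {
      tot <- tot + mmd_pair(grp[[i]], grp[[j]])
      np <- np + 1
    }
  }
  tot / np
}

#' Unbiased distance correlation (DCorr) effect size
#'
#' Quantifies the magnitude of association between multivariate measurements
#' and a covariate, for linear and nonlinear dependence alike, via the
#' bias-corrected (U-centered) distance correlation. Categorical covariates
#' are one-hot encoded before computing their Euclidean distances. Constant
#' input yields 0 by convention (flagged in the details).
#'
#' @param X numeric matrix of measurements (rows are observations).
#' @param y numeric vector, factor, or character covariate.
#' @return a `"replicability_stat"` (details: `dcov`, `dvar_x`, `dvar_y`,
#'   `degenerate`).
#' @export
dcorr_effect <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4L) stop("unbiased distance correlation needs N >= 4")
  if (is.character(y) || is.factor(y)) {
    y <- stats::model.matrix(~ factor(y) - 1)
  }
  Y <- as.matrix(y)
  if (nrow(Y) != n) stop("X and y must have the same number of observations")
  degenerate <- all(apply(X, 2, stats::sd) == 0) || all(apply(Y, 2, stats::sd) == 0)
  if (degenerate) {
    return(new_stat("dcorr", 0, list(dcov = 0, dvar_x = 0, dvar_y = 0, degenerate = TRUE)))
  }
  A <- u_center(as.matrix(stats::dist(X)))
  B <- u_center(as.matrix(stats::dist(Y)))
  dcov <- u_inner(A, B)
  vx <- u_inner(A, A)
  vy <- u_inner(B, B)
  val <- if (vx <= 0 || vy <= 0) 0 else dcov / sqrt(vx * vy)
  new_stat("dcorr", val, list(dcov = dcov, dvar_x = vx, dvar_y = vy, degenerate = FALSE))
}

# U-centering of a distance matrix (bias-corrected double centering)
u_center <- function(D) {
  n <- nrow(D)
  r <- rowSums(D)
  s <- sum(D)
  A <- D - outer(r, rep(1, n)) / (n - 2) - outer(rep(1, n), r) / (n - 2) +
    s / ((n - 1) * (n - 2))
  diag(A) <- 0
  A
}

u_inner <- function(A, B) {
  n <- nrow(A)
  sum(A * B) / (n * (n - 3))
}
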