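# Independent brute-force oracles used to pin down expected values.
# These deliberately share no code with the package internals: the
# discriminability oracle is a naive triple loop over (anchor, within-mate,
# across-measurement) comparisons.

discr_oracle <- function(D, ids) {
  D <- as.matrix(D)
  N <- length(ids)
  per <- rep(NA_real_, N)
  for (j in seq_len(N)) {
    mates <- setdiff(which(ids == ids[j]), j)
    if (!length(mates)) next
    viol <- 0
    ncomp <- 0
    for (jp in mates) {
      for (k in which(ids != ids[j])) {
        ncomp <- ncomp + 1
        if (D[j, k] < D[j, jp]) viol <- viol + 1
        else if (D[j, k] == D[j, jp]) viol <- viol + 0.5
      }
    }
    per[j] <- 1 - viol / ncomp
  }
  list(statistic = mean(per, na.rm = TRUE), per_measurement = per)
}

# random test instance: n items, random replicate counts, d dims; optional
# engineered ties from snapping features to a coarse lattice
random_instance <- function(n = 5, smax = 4, d = 2, ties = FALSE) {
  si <- sample(2:smax, n, replace = TRUE)
  ids <- rep(sprintf("i%02d", seq_len(n)), times = si)
  X <- matrix(rnorm(length(ids) * d), ncol = d)
  if (ties) X <- round(X * 2) / 2
  measurement_set(X, ids = ids)
}

expect_valid_discr <- function(fit) {
  testthat::expect_true(fit$statistic >= 0 && fit$statistic <= 1)
  ok <- !is.na(fit$per_measurement)
  testthat::expect_equal(mean(fit$per_measurement[ok]), fit$statistic)
}
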