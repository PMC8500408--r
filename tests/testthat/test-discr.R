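test_that("perfectly separated items reach exactly 1, with unit per-measurement values", {
  ms <- measurement_set(matrix(c(0, 1, 10, 11), ncol = 1),
                        ids = c("A", "A", "B", "B"))
  fit <- discr(ms)
  expect_identical(fit$statistic, 1)
  expect_identical(fit$f, 0)
  expect_equal(fit$per_measurement, rep(1, 4))
  expect_equal(fit$g, 4) # 2 items x s(s-1)
})

test_that("the 4-point interleaved example reproduces the oracle-derived decomposition", {
  # A = {0, 1}, B = {0.5, 3}: brute-force enumeration gives f = 5 of 8
  # comparisons violated, per-measurement (1/2, 1/2, 0, 1/2), Discr = 0.375
  ms <- measurement_set(matrix(c(0, 1, 0.5, 3), ncol = 1),
                        ids = c("A", "A", "B", "B"))
  oracle <- discr_oracle(as.matrix(dist(ms$features)), ms$ids)
  expect_equal(oracle$statistic, 0.375)

  fit <- discr(ms)
  expect_equal(fit$statistic, 0.375)
  expect_equal(fit$f, 5)
  expect_equal(fit$n_comparisons, 8)
  expect_equal(fit$per_measurement, c(0.5, 0.5, 0, 0.5))
  # balanced s=2, tie-free: Definition-style closed form with N(N-1)-g
  N <- 4; g <- fit$g
  expect_equal(fit$statistic, 1 - fit$f / (N * (N - 1) - g))
})

test_that("the balanced 10x2 design has g = 20 and 360 comparisons", {
  ms <- sim_1d("discriminable")
  fit <- discr(ms)
  expect_equal(dim(compute_distances(ms)$values), c(20L, 20L))
  expect_equal(fit$g, 20)
  expect_equal(fit$n_comparisons, 20 * 19 - 20)
})

test_that("optimized implementation equals the triple-loop oracle on random instances", {
  set.seed(20240917)
  for (rep in 1:60) {
    ms <- random_instance(n = sample(2:8, 1), smax = 4, d = sample(1:3, 1),
                          ties = rep %% 2 == 0)
    D <- as.matrix(dist(ms$features))
    fit <- discr(ms)
    oracle <- discr_oracle(D, ms$ids)
    expect_identical(fit$statistic, oracle$statistic)
    expect_identical(fit$per_measurement, oracle$per_measurement)
    expect_valid_discr(fit)
  }
})

test_that("singleton items are excluded with a warning, matching oracle on the rest", {
  set.seed(5)
  X <- matrix(rnorm(7), ncol = 1)
  ids <- c("a", "a", "b", "b", "c", "c", "lone")
  expect_warning(fit <- discr(measurement_set(X, ids)), "single measurement")
  expect_true(is.na(fit$per_measurement[7]))
  expect_equal(fit$statistic, discr_oracle(as.matrix(dist(X)), ids)$statistic)
  expect_identical(fit$excluded, "lone")
  # fewer than two items with replicates is an error
  expect_error(discr(measurement_set(matrix(1:3, ncol = 1), c("a", "a", "b"))),
               "at least 2 items")
})

test_that("the statistic depends on distances only through their ranks", {
  set.seed(99)
  for (rep in 1:10) {
    ms <- random_instance(n = 5, smax = 3, d = 2)
    D <- compute_distances(ms)
    base <- discr(D)$statistic
    for (f in list(function(x) x^1.7, function(x) log1p(x), function(x) sqrt(x))) {
      Dt <- as_distance_matrix(f(D$values), D$ids)
      expect_identical(discr(Dt)$statistic, base)
    }
  }
})

test_that("rigid motions of Euclidean features leave the statistic unchanged", {
  set.seed(123)
  for (rep in 1:10) {
    ms <- random_instance(n = 6, smax = 3, d = 3)
    base <- discr(ms)$statistic
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3))) # random orthogonal matrix
    shifted <- measurement_set(ms$features %*% Q + rep(1, nrow(ms$features)) %o% rnorm(3),
                               ids = ms$ids)
    expect_equal(discr(shifted)$statistic, base)
  }
})

test_that("exchangeable data sit at 0.5 on average", {
  set.seed(314)
  nrep <- 60
  vals <- replicate(nrep, {
    ids <- rep(sprintf("i%d", 1:8), each = 2)
    discr(measurement_set(matrix(rnorm(16), ncol = 1), ids))$statistic
  })
  se <- sd(vals) / sqrt(nrep)
  expect_lt(abs(mean(vals) - 0.5), 3 * se + 1e-8)
})

test_that("discr accessors and methods are consistent", {
  ms <- sim_1d("discriminable")
  fit <- discr(ms)
  expect_equal(unname(coef(fit)), fit$statistic)
  expect_equal(discr_per_measurement(compute_distances(ms)), fit$per_measurement)
  s <- summary(fit)
  expect_s3_class(s, "summary.discr")
  expect_output(print(fit), "Discr = 1")
})
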