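test_that("p-values obey the add-one formula and are never zero", {
  ms <- sim_1d("discriminable")
  res <- test_one_sample(ms, "discr", n_perm = 100, seed = 3)
  expect_length(res$null_sample, 100)
  expect_equal(res$p_value,
               (1 + sum(res$null_sample >= res$observed)) / 101)
  expect_gt(res$p_value, 0)
  # a perfectly separated design beats every permutation at this seed
  expect_equal(res$observed, 1)
  expect_equal(res$p_value, 1 / 101)

  # n_perm = 1 forces p into {1/2, 1}
  r1 <- test_one_sample(ms, "discr", n_perm = 1, seed = 5)
  expect_true(r1$p_value %in% c(0.5, 1))
})

test_that("identical seeds give identical results; different seeds differ", {
  ms <- sim_2d("gaussian", seed = 4)
  a <- test_one_sample(ms, "discr", n_perm = 50, seed = 11)
  b <- test_one_sample(ms, "discr", n_perm = 50, seed = 11)
  expect_identical(a$null_sample, b$null_sample)
  expect_identical(a$p_value, b$p_value)
  c <- test_one_sample(ms, "discr", n_perm = 50, seed = 12)
  expect_false(identical(a$null_sample, c$null_sample))
})

test_that("one-sample p-values are super-uniform under exchangeability", {
  set.seed(77)
  nrep <- 120
  ps <- replicate(nrep, {
    ids <- rep(sprintf("i%d", 1:8), each = 2)
    ms <- measurement_set(matrix(rnorm(32), ncol = 2), ids)
    test_one_sample(ms, "discr", n_perm = 60, seed = sample.int(1e6, 1))$p_value
  })
  for (alpha in c(0.05, 0.1)) {
    se <- sqrt(alpha * (1 - alpha) / nrep)
    expect_lte(mean(ps <= alpha), alpha + 3 * se)
  }
})

test_that("the two-sample comparison detects a maximal replicability difference", {
  set.seed(1)
  ids <- rep(sprintf("i%02d", 1:16), each = 2)
  mu <- rnorm(16, sd = 10)
  good <- measurement_set(matrix(mu[rep(1:16, each = 2)] + rnorm(32, sd = 0.01)), ids)
  bad <- measurement_set(matrix(rnorm(32)), ids) # no item information
  res <- test_two_sample(good, bad, "discr", n_perm = 500, seed = 2)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$observed, 0.4)

  # antisymmetry of the observed statistic
  rev <- test_two_sample(bad, good, "discr", n_perm = 10, seed = 2)
  expect_equal(rev$observed, -res$observed)
})

test_that("literally identical strategies yield a degenerate null and p = 1", {
  ms <- sim_2d("gaussian", seed = 9)
  res <- test_two_sample(ms, ms, "discr", n_perm = 50, seed = 1)
  expect_equal(res$observed, 0)
  expect_true(all(res$null_sample == 0))
  expect_equal(res$p_value, 1)
})

test_that("mismatched designs and undefined statistics are rejected", {
  ms1 <- sim_2d("gaussian", seed = 1)
  ms2 <- sim_2d("cross", seed = 1)
  expect_error(test_two_sample(ms1, ms2, "discr"), "same items")
  D <- compute_distances(sim_1d("discriminable"))
  expect_error(test_one_sample(D, stat = "i2c2"), "feature input")
  ms3 <- sim_2d("gaussian", seed = 2)
  expect_error(test_one_sample(ms3, stat = "icc"), "univariate")
})

test_that("all registered statistics run through both tests", {
  ms <- sim_2d("gaussian", seed = 6, n_total = 64)
  ms2 <- sim_2d("gaussian", seed = 7, n_total = 64)
  for (st in c("discr", "picc", "i2c2", "fingerprint", "kernel")) {
    r1 <- test_one_sample(ms, st, n_perm = 20, seed = 1)
    expect_true(r1$p_value > 0 && r1$p_value <= 1)
    r2 <- test_two_sample(ms, ms2, st, n_perm = 20, seed = 1)
    expect_true(r2$p_value > 0 && r2$p_value <= 1)
  }
})
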