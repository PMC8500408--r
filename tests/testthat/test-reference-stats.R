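test_that("ICC hits its boundary cases and matches the ANOVA route", {
  # zero within-item variance, distinct items -> 1
  x <- c(1, 1, 5, 5, 9, 9)
  ids <- rep(c("a", "b", "c"), each = 2)
  expect_equal(icc(x, ids)$value, 1)

  # single population: near zero for many items
  set.seed(8)
  ids2 <- rep(sprintf("i%d", 1:200), each = 2)
  expect_lt(abs(icc(rnorm(400), ids2)$value), 0.1)

  expect_error(icc(rep(2, 6), ids), "constant")

  # textbook identity: recompute from lm/anova mean squares on a 3-item example
  x3 <- c(8.1, 7.9, 5.2, 5.6, 9.0, 9.4)
  st <- icc(x3, ids)
  ms_tab <- anova(lm(x3 ~ factor(ids)))
  msb <- ms_tab$`Mean Sq`[1]; msw <- ms_tab$`Mean Sq`[2]
  expect_equal(st$value, (msb - msw) / (msb + (2 - 1) * msw))
  expect_equal(st$details$msb, msb)
  expect_equal(st$details$msw, msw)
})

test_that("PICC reduces to ICC in 1-D and matches a by-hand SVD oracle", {
  set.seed(21)
  ids <- rep(sprintf("i%d", 1:6), each = 2)
  x <- rnorm(12)
  ms1 <- measurement_set(matrix(x, ncol = 1), ids)
  expect_equal(picc(ms1)$value, icc(x, ids)$value)

  # variance confined to axis 1: PICC equals ICC of that axis
  X <- cbind(x, 0)
  expect_equal(picc(measurement_set(X, ids))$value, icc(x, ids)$value)

  # random 2-D instance against an independent SVD + ANOVA-sum oracle
  X2 <- matrix(rnorm(24), ncol = 2)
  ms2 <- measurement_set(X2, ids)
  Xc <- scale(X2, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  scores <- sv$u[, 1] * sv$d[1]
  f <- factor(ids); n <- nlevels(f); N <- length(scores)
  m <- tapply(scores, f, mean); g <- mean(scores)
  msb <- sum(2 * (m - g)^2) / (n - 1)
  msw <- sum((scores - m[f])^2) / (N - n)
  expect_equal(abs(picc(ms2)$value), abs((msb - msw) / (msb + msw)))
})

test_that("I2C2 is 1 for pure signal and truncated to 0 for pure noise", {
  ids <- rep(sprintf("i%d", 1:5), each = 2)
  mu <- matrix(rnorm(10, sd = 4), 5, 2)
  ms <- measurement_set(mu[rep(1:5, each = 2), ], ids)
  expect_equal(i2c2(ms)$value, 1)

  set.seed(99)
  noise <- measurement_set(matrix(rnorm(40), ncol = 2), rep(sprintf("i%d", 1:10), each = 2))
  v <- i2c2(noise)$value
  expect_gte(v, 0)
  expect_lt(v, 0.35)
})

test_that("the fingerprint index matches exhaustive nearest-neighbour matching", {
  # perfectly separated items -> 1
  ms <- measurement_set(matrix(c(0, 10, 20, 0.2, 10.2, 20.2), ncol = 1),
                        ids = rep(c("a", "b", "c"), 2),
                        sessions = rep(1:2, each = 3))
  expect_equal(fingerprint_index(ms)$value, 1)

  # derived example: s1 = {A:0, B:0.5}, s2 = {A:1, B:3} -> 1/2 both directions
  ms2 <- measurement_set(matrix(c(0, 0.5, 1, 3), ncol = 1),
                         ids = c("A", "B", "A", "B"),
                         sessions = c(1, 1, 2, 2))
  fp <- fingerprint_index(ms2)
  expect_equal(fp$value, 0.5)
  expect_equal(fp$details$match_12, 0.5)
  expect_equal(fp$details$match_21, 0.5)

  # cyclic shift of well-separated session-2 labels -> 0
  x <- c(0, 10, 20, 10.1, 20.1, 0.1) # session-2 block shifted by one item
  ms3 <- measurement_set(matrix(x, ncol = 1),
                         ids = c("a", "b", "c", "a", "b", "c"),
                         sessions = rep(1:2, each = 3))
  expect_equal(fingerprint_index(ms3)$value, 0)

  # equidistant tie resolves toward a mismatch
  ms4 <- measurement_set(matrix(c(0, 2, 1, 3), ncol = 1),
                         ids = c("A", "B", "A", "B"), sessions = c(1, 1, 2, 2))
  expect_equal(fingerprint_index(ms4)$details$match_12, 0.5) # A's NN is tied A/B
})

test_that("kernel statistic equals a direct unbiased MMD^2 double sum", {
  # identical point sets: unbiased estimate <= 0, reported value clamped at 0
  X <- rbind(matrix(c(0, 0, 1, 1, 2, 0), 3, 2, byrow = TRUE),
             matrix(c(0, 0, 1, 1, 2, 0), 3, 2, byrow = TRUE))
  ms <- measurement_set(X, rep(c("a", "b"), each = 3))
  ks <- kernel_stat(ms)
  expect_equal(ks$value, 0)
  expect_lte(ks$details$raw, 0)

  # far-separated tight clusters saturate the statistic: under the median
  # bandwidth (which lands on the cross-cluster distance) the ceiling is
  # 2 * (1 - exp(-1/2)); a weakly separated pair stays well below it
  set.seed(3)
  mk <- function(sep, sd) {
    Y <- rbind(matrix(rnorm(20, sd = sd), ncol = 2),
               matrix(rnorm(20, sd = sd) + sep, ncol = 2))
    kernel_stat(measurement_set(Y, rep(c("a", "b"), each = 10)))$value
  }
  ceiling_val <- 2 * (1 - exp(-0.5))
  expect_lt(abs(mk(100, 1e-3) - ceiling_val), 0.01)
  expect_lt(abs(mk(1000, 1e-3) - ceiling_val), 0.01)
  expect_lt(mk(1, 1), ceiling_val - 0.2)

  # fixed 6-point instance vs explicit double sums
  Z <- matrix(c(0, 0, 1, 0, 0, 2, 3, 1, 2, 2, 4, 0), ncol = 2, byrow = TRUE)
  ids <- rep(c("a", "b"), each = 3)
  D <- as.matrix(dist(Z))
  sigma <- median(D[upper.tri(D)])
  K <- exp(-D^2 / (2 * sigma^2))
  a <- 1:3; b <- 4:6
  s_aa <- 0; for (i in a) for (j in a) if (i != j) s_aa <- s_aa + K[i, j]
  s_bb <- 0; for (i in b) for (j in b) if (i != j) s_bb <- s_bb + K[i, j]
  s_ab <- 0; for (i in a) for (j in b) s_ab <- s_ab + K[i, j]
  mmd <- s_aa / 6 + s_bb / 6 - 2 * s_ab / 9
  expect_equal(kernel_stat(measurement_set(Z, ids))$details$raw, mmd)
})

test_that("unbiased distance correlation matches a brute-force U-centering oracle", {
  u_center_oracle <- function(D) {
    n <- nrow(D)
    A <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      A[i, j] <- D[i, j] - sum(D[i, ]) / (n - 2) - sum(D[, j]) / (n - 2) +
        sum(D) / ((n - 1) * (n - 2))
    }
    A
  }
  X <- matrix(c(0.1, 1.4, -2, 0.7, 3.1), ncol = 1)
  y <- c(1, 0, 2.5, -1, 0.3)
  A <- u_center_oracle(as.matrix(dist(X)))
  B <- u_center_oracle(as.matrix(dist(y)))
  n <- 5
  dcov <- sum(A * B) / (n * (n - 3))
  dvx <- sum(A * A) / (n * (n - 3))
  dvy <- sum(B * B) / (n * (n - 3))
  expect_equal(dcorr_effect(X, y)$value, dcov / sqrt(dvx * dvy))

  # dependence limits
  set.seed(10)
  x <- matrix(rnorm(300), ncol = 1)
  expect_gt(dcorr_effect(x, 3 * x[, 1] - 2)$value, 0.95)
  expect_lt(abs(dcorr_effect(x, rnorm(300))$value), 0.15)
  # constant input flagged
  z <- dcorr_effect(matrix(1, 10, 1), rnorm(10))
  expect_equal(z$value, 0)
  expect_true(z$details$degenerate)
  # categorical covariates are one-hot encoded
  g <- rep(c("m", "f"), each = 150)
  xx <- matrix(rnorm(300, mean = ifelse(g == "m", 0, 3)), ncol = 1)
  expect_gt(dcorr_effect(xx, g)$value, 0.3)
})

test_that("the three 1-D settings reproduce the qualitative statistic contrasts", {
  d_disc <- sim_1d("discriminable")
  d_off <- sim_1d("offset")
  d_out <- sim_1d("outlier")

  r_disc <- discr(d_disc)$statistic
  r_off <- discr(d_off)$statistic
  r_out <- discr(d_out)$statistic
  expect_identical(r_disc, 1)
  expect_lt(r_off, r_disc)
  expect_gt(r_off, 0.5) # still structured data

  # fingerprint collapses by more than 5x under the offset
  expect_lte(fingerprint_index(d_off)$value, fingerprint_index(d_disc)$value / 5)

  # kernel drops under the offset while ICC barely moves
  expect_lt(kernel_stat(d_off)$value, kernel_stat(d_disc)$value)
  icc_disc <- icc(d_disc$features[, 1], d_disc$ids)$value
  icc_off <- icc(d_off$features[, 1], d_off$ids)$value
  expect_gt(icc_disc, 0.95)
  expect_gt(icc_off, 0.85) # ICC stays high, blind to the offset

  # outliers drive ICC negative but Discr barely moves
  expect_lt(icc(d_out$features[, 1], d_out$ids)$value, 0)
  expect_gte(r_out, r_disc - 0.1)
})
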