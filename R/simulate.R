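#' One-dimensional benchmark settings
#'
#' Three deterministic univariate designs, each with 10 items measured
#' twice, that exercise characteristic notions of replicability:
#'
#' * `discriminable`: item centers at 1..10, measurements at center ± 0.1 —
#'   every within-item distance is below every across-item distance, so
#'   Discr is exactly 1.
#' * `offset`: the second measurement of every item is displaced by 1.2
#'   (1.2 × the center spacing), so it lies beyond the neighbouring item's
#'   first measurement. The data remain structured, but nearest-neighbour
#'   identification breaks down almost everywhere.
#' * `outlier`: as `discriminable`, but two items carry an outlier second
#'   measurement — item 1 displaced by −1.5 and item 2 by +40. The outliers
#'   inflate the within-item mean squares past the between-item mean
#'   squares, driving the ANOVA ICC negative, while only 4 of 20
#'   measurements are affected so Discr stays high.
#'
#' The designs are deterministic so the qualitative contrasts between the
#' statistics are reproducible exactly; `jitter` adds optional Gaussian
#' measurement noise.
#'
#' @param setting `"discriminable"`, `"offset"`, or `"outlier"`.
#' @param jitter standard deviation of optional added noise (default 0,
#'   i.e. deterministic).
#' @param seed seed used when `jitter > 0`.
#' @return a [measurement_set()] with session labels 1 and 2.
#' @export
sim_1d <- function(setting = c("discriminable", "offset", "outlier"),
                   jitter = 0, seed = 1L) {
  setting <- match.arg(setting)
  centers <- 1:10
  delta <- 0.1
  m1 <- centers - delta
  m2 <- centers + delta
  if (setting == "offset") m2 <- m2 + 1.2
  if (setting == "outlier") {
    m2[1] <- m2[1] - 1.5
    m2[2] <- m2[2] + 40
  }
  x <- c(m1, m2)
  if (jitter > 0) x <- with_seed(seed, x + stats::rnorm(length(x), sd = jitter))
  measurement_set(matrix(x, ncol = 1),
                  ids = rep(sprintf("s%02d", centers), 2L),
                  sessions = rep(1:2, each = 10L))
}

sim2d_settings <- function() c("gaussian", "cross", "ball_circle", "xor", "no_signal")

# within-item (accidental) noise sd for a setting at a given noise_scale
noise_sd <- function(setting, noise_scale) {
  base <- c(gaussian = 0.2, cross = 0.2, ball_circle = 0.2, xor = 0.2, no_signal = 1)
  unname(base[setting]) * noise_scale
}

gaussian_grid <- function() {
  g <- expand.grid(x = 0:3, y = 0:3)
  g$class <- ifelse((g$x + g$y) %% 2 == 0, "A", "B") # alternating assignment
  g
}

#' Two-dimensional benchmark settings
#'
#' Five generative settings, each producing `n_total` (default 128)
#' two-dimensional measurements with item and class labels. `noise_scale`
#' multiplies the within-item (accidental) noise standard deviation, so
#' sweeping it traces out the replicability-versus-variance curves.
#'
#' * `gaussian`: 16 items, spherically symmetric Gaussians centered on a
#'   4×4 unit-spaced grid (noise sd `0.2 * noise_scale`); the 16 items are
#'   split into two classes of 8 by alternating grid assignment.
#' * `cross`: 2 items with the same mean and different diagonal
#'   covariances — sds (1, √0.05) and (√0.05, 1) — plus isotropic noise of
#'   sd `0.2 * noise_scale`.
#' * `ball_circle`: one item uniform in the unit ball, the other on the
#'   unit circle, both plus isotropic Gaussian noise of sd
#'   `0.2 * noise_scale`.
#' * `xor`: 2 items, each an equal mixture of two spherical Gaussians (sd
#'   `0.2 * noise_scale`) with means arranged in an XOR pattern: item 1 at
#'   (0,1) and (1,0), item 2 at (0,0) and (1,1).
#' * `no_signal`: both items from the same isotropic Gaussian (sd
#'   `noise_scale`); population discriminability 0.5.
#'
#' For the two-item settings the class label equals the item label.
#'
#' @param setting one of `"gaussian"`, `"cross"`, `"ball_circle"`, `"xor"`,
#'   `"no_signal"`.
#' @param noise_scale positive multiplier of the within-item noise sd.
#' @param n_total total number of measurements; must be divisible by the
#'   setting's item count (16 for gaussian, 2 otherwise).
#' @param seed integer seed; generation is deterministic given the seed.
#' @return a [measurement_set()] with classes and session labels.
#' @export
sim_2d <- function(setting = sim2d_settings(), noise_scale = 1,
                   n_total = 128L, seed = 1L) {
  setting <- match.arg(setting)
  stopifnot(noise_scale >= 0, n_total >= 4L)
  n_items <- if (setting == "gaussian") 16L else 2L
  if (n_total %% n_items != 0L) {
    stop("n_total must be divisible by the item count (", n_items, ") of setting '",
         setting, "'")
  }
  s <- n_total %/% n_items
  tau <- noise_sd(setting, noise_scale)
  with_seed(seed, {
    if (setting == "gaussian") {
      g <- gaussian_grid()
      mu <- as.matrix(g[, c("x", "y")])
      X <- mu[rep(1:16, each = s), ] + matrix(stats::rnorm(2 * n_total, sd = tau), ncol = 2)
      ids <- rep(sprintf("i%02d", 1:16), each = s)
      classes <- rep(g$class, each = s)
    } else if (setting == "cross") {
      sig <- sqrt(0.05)
      x1 <- cbind(stats::rnorm(s, sd = 1), stats::rnorm(s, sd = sig))
      x2 <- cbind(stats::rnorm(s, sd = sig), stats::rnorm(s, sd = 1))
      X <- rbind(x1, x2) + matrix(stats::rnorm(2 * n_total, sd = tau), ncol = 2)
      ids <- rep(c("i01", "i02"), each = s)
      classes <- ids
    } else if (setting == "ball_circle") {
      r <- sqrt(stats::runif(s)) # uniform in the unit ball
      a1 <- stats::runif(s, 0, 2 * pi)
      x1 <- cbind(r * cos(a1), r * sin(a1))
      a2 <- stats::runif(s, 0, 2 * pi)
      x2 <- cbind(cos(a2), sin(a2))
      X <- rbind(x1, x2) + matrix(stats::rnorm(2 * n_total, sd = tau), ncol = 2)
      ids <- rep(c("i01", "i02"), each = s)
      classes <- ids
    } else if (setting == "xor") {
      mu1 <- rbind(c(0, 1), c(1, 0))
      mu2 <- rbind(c(0, 0), c(1, 1))
      comp1 <- sample(1:2, s, replace = TRUE)
      comp2 <- sample(1:2, s, replace = TRUE)
      X <- rbind(mu1[comp1, ], mu2[comp2, ]) +
        matrix(stats::rnorm(2 * n_total, sd = tau), ncol = 2)
      ids <- rep(c("i01", "i02"), each = s)
      classes <- ids
    } else { # no_signal
      X <- matrix(stats::rnorm(2 * n_total, sd = tau), ncol = 2)
      ids <- rep(c("i01", "i02"), each = s)
      classes <- ids
    }
    measurement_set(X, ids = ids, classes = classes,
                    sessions = rep(seq_len(s), times = n_items))
  })
}

# class-conditional log-density of an equal-weight isotropic Gaussian mixture
log_mix_density <- function(x, mu, sd) {
  # x: n x 2; mu: k x 2
  n <- nrow(x)
  ll <- matrix(0, n, nrow(mu))
  for (k in seq_len(nrow(mu))) {
    ll[, k] <- stats::dnorm(x[, 1], mu[k, 1], sd, log = TRUE) +
      stats::dnorm(x[, 2], mu[k, 2], sd, log = TRUE)
  }
  m <- apply(ll, 1, max)
  m + log(rowMeans(exp(ll - m)))
}

# deterministic quadrature point sets for the ball_circle densities
sunflower_ball <- function(n) {
  k <- seq_len(n)
  r <- sqrt((k - 0.5) / n)
  th <- 2 * pi * k * (sqrt(5) - 1) / 2
  cbind(r * cos(th), r * sin(th))
}

circle_points <- function(n) {
  th <- 2 * pi * (seq_len(n) - 0.5) / n
  cbind(cos(th), sin(th))
}

#' Bayes accuracy of a simulation setting
#'
#' The best achievable class-prediction accuracy under the true generative
#' densities of a [sim_2d()] setting, estimated by Monte Carlo: draw
#' labelled points from the model, classify each by the larger true
#' class-conditional density (ties broken at random), and report the
#' fraction correct. This is the ceiling any classifier can reach, so it is
#' the natural downstream-performance oracle against which replicability
#' statistics are compared across a noise sweep.
#'
#' For `gaussian`, `cross`, and `xor` the class-conditional densities are
#' (mixtures of) Gaussians in closed form; for `ball_circle` the uniform
#' ball/circle components are integrated numerically over fixed
#' low-discrepancy point sets; `no_signal` has identical classes and Bayes
#' accuracy 1/2.
#'
#' @param setting a [sim_2d()] setting name.
#' @param noise_scale noise multiplier, as in [sim_2d()].
#' @param n_mc number of Monte Carlo draws.
#' @param seed integer seed.
#' @return scalar accuracy in \[0.5, 1\].
#' @export
bayes_accuracy <- function(setting = sim2d_settings(), noise_scale = 1,
                           n_mc = 20000L, seed = 1L) {
  setting <- match.arg(setting)
  tau <- noise_sd(setting, noise_scale)
  if (tau <= 0 && setting %in% c("cross", "ball_circle")) {
    stop("bayes_accuracy needs noise_scale > 0 for setting '", setting, "'")
  }
  with_seed(seed, {
    if (setting == "no_signal") {
      return(0.5) # identical class-conditional densities; any rule is a coin flip
    }
    if (setting == "gaussian") {
      g <- gaussian_grid()
      muA <- as.matrix(g[g$class == "A", c("x", "y")])
      muB <- as.matrix(g[g$class == "B", c("x", "y")])
      lab <- sample(c("A", "B"), n_mc, replace = TRUE)
      mu <- rbind(muA, muB)
      pick <- ifelse(lab == "A", 0L, 8L) + sample(1:8, n_mc, replace = TRUE)
      x <- mu[pick, ] + matrix(stats::rnorm(2 * n_mc, sd = tau), ncol = 2)
      dA <- log_mix_density(x, muA, tau)
      dB <- log_mix_density(x, muB, tau)
    } else if (setting == "cross") {
      sig <- sqrt(0.05)
      sd1 <- sqrt(c(1, 0.05) + tau^2)
      sd2 <- rev(sd1)
      lab <- sample(c("A", "B"), n_mc, replace = TRUE)
      x <- matrix(stats::rnorm(2 * n_mc), ncol = 2)
      x[lab == "A", ] <- sweep(x[lab == "A", , drop = FALSE], 2, sd1, `*`)
      x[lab == "B", ] <- sweep(x[lab == "B", , drop = FALSE], 2, sd2, `*`)
      dA <- stats::dnorm(x[, 1], 0, sd1[1], log = TRUE) + stats::dnorm(x[, 2], 0, sd1[2], log = TRUE)
      dB <- stats::dnorm(x[, 1], 0, sd2[1], log = TRUE) + stats::dnorm(x[, 2], 0, sd2[2], log = TRUE)
    } else if (setting == "xor") {
      muA <- rbind(c(0, 1), c(1, 0))
      muB <- rbind(c(0, 0), c(1, 1))
      lab <- sample(c("A", "B"), n_mc, replace = TRUE)
      comp <- sample(1:2, n_mc, replace = TRUE)
      mu <- ifelse(lab == "A", 0L, 2L) + comp
      x <- rbind(muA, muB)[mu, ] + matrix(stats::rnorm(2 * n_mc, sd = tau), ncol = 2)
      dA <- log_mix_density(x, muA, tau)
      dB <- log_mix_density(x, muB, tau)
    } else { # ball_circle
      qb <- sunflower_ball(256L)
      qc <- circle_points(256L)
      lab <- sample(c("A", "B"), n_mc, replace = TRUE)
      r <- sqrt(stats::runif(n_mc))
      th <- stats::runif(n_mc, 0, 2 * pi)
      base <- cbind(r * cos(th), r * sin(th))
      onc <- lab == "B"
      base[onc, ] <- cbind(cos(th[onc]), sin(th[onc]))
      x <- base + matrix(stats::rnorm(2 * n_mc, sd = tau), ncol = 2)
      dA <- log_mix_density(x, qb, tau)
      dB <- log_mix_density(x, qc, tau)
    }
    tie <- dA == dB
    guess <- ifelse(dA > dB, "A", "B")
    if (any(tie)) guess[tie] <- sample(c("A", "B"), sum(tie), replace = TRUE)
    mean(guess == lab)
  })
}

#' Power of the replicability tests across simulation settings
#'
#' Monte Carlo power analysis: for each (setting, noise_scale, statistic)
#' cell, `n_iter` datasets are generated, the requested permutation test is
#' run on each, and power is the fraction of p-values at or below `alpha`.
#' In `two_sample` mode the base strategy is compared against a degraded
#' variant of the same draw (the same measurements plus additional isotropic
#' noise, `degrade` times the setting's noise sd), so the alternative
#' \eqn{R^{(1)} > R^{(2)}} holds by construction except under `no_signal`-like
#' saturation.
#'
#' @param settings character vector of [sim_2d()] settings.
#' @param noise_scales numeric vector of noise multipliers.
#' @param test `"one_sample"` or `"two_sample"`.
#' @param stats character vector of statistics (see [test_one_sample()]).
#' @param n_iter Monte Carlo iterations per cell (default 500).
#' @param n_perm permutations per test.
#' @param alpha rejection level.
#' @param n_total measurements per dataset.
#' @param degrade noise multiplier for the degraded strategy in
#'   `two_sample` mode.
#' @param seed integer seed.
#' @return data.frame with columns `setting`, `noise_scale`, `stat`,
#'   `power`, `n_iter`.
#' @export
power_curve <- function(settings = sim2d_settings(), noise_scales = 1,
                        test = c("one_sample", "two_sample"),
                        stats = "discr", n_iter = 500L, n_perm = 100L,
                        alpha = 0.05, n_total = 128L, degrade = 2,
                        seed = 1L) {
  test <- match.arg(test)
  grid <- expand.grid(setting = settings, noise_scale = noise_scales,
                      stat = stats, stringsAsFactors = FALSE)
  grid$power <- NA_real_
  grid$n_iter <- n_iter
  for (i in seq_len(nrow(grid))) {
    st <- grid$setting[i]
    ns <- grid$noise_scale[i]
    stat <- grid$stat[i]
    rej <- 0L
    for (b in seq_len(n_iter)) {
      iter_seed <- seed + 7919L * i + b
      ms <- sim_2d(st, noise_scale = ns, n_total = n_total, seed = iter_seed)
      res <- if (test == "one_sample") {
        test_one_sample(ms, stat = stat, n_perm = n_perm, seed = iter_seed + 1L)
      } else {
        ms2 <- ms
        tau <- noise_sd(st, ns)
        ms2$features <- ms2$features + with_seed(iter_seed + 2L,
          matrix(stats::rnorm(length(ms$features), sd = degrade * tau),
                 ncol = ncol(ms$features)))
        test_two_sample(ms, ms2, stat = stat, n_perm = n_perm, seed = iter_seed + 3L)
      }
      if (res$p_value <= alpha) rej <- rej + 1L
    }
    grid$power[i] <- rej / n_iter
  }
  grid
}
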