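#' Construct a strategy panel
#'
#' The grid of replicability values across analysis strategies and datasets
#' that drives strategy ranking, per-stage attribution, and the
#' effect-size-versus-replicability regression. Dataset weights default to
#' being proportional to the number of measurements per dataset (equal if
#' sizes are unknown) and are normalized to sum to one, so the mean Discr of
#' a strategy is a weighted sum of its per-dataset values.
#'
#' @param discr_values S×K numeric matrix of replicability values
#'   (strategies in rows, datasets in columns); dimnames are used as
#'   strategy and dataset labels.
#' @param weights optional length-K positive dataset weights (e.g. dataset
#'   sizes); normalized internally.
#' @param strategy_codes optional data.frame with one row per strategy and
#'   one factor column per analysis stage (for [one_factor_analysis()]).
#' @param effect_sizes optional S×K matrix of downstream effect sizes (e.g.
#'   DCorr against a covariate) aligned with `discr_values`.
#' @return an object of class `"strategy_panel"`.
#' @export
strategy_panel <- function(discr_values, weights = NULL, strategy_codes = NULL,
                           effect_sizes = NULL) {
  discr_values <- as.matrix(discr_values)
  if (anyNA(discr_values)) stop("discr_values must not contain missing values")
  S <- nrow(discr_values); K <- ncol(discr_values)
  if (is.null(rownames(discr_values))) rownames(discr_values) <- sprintf("strategy%02d", seq_len(S))
  if (is.null(colnames(discr_values))) colnames(discr_values) <- sprintf("dataset%02d", seq_len(K))
  if (is.null(weights)) weights <- rep(1, K)
  if (length(weights) != K || any(weights <= 0)) {
    stop("'weights' must be positive, one per dataset")
  }
  weights <- weights / sum(weights)
  if (!is.null(strategy_codes)) {
    strategy_codes <- as.data.frame(strategy_codes)
    if (nrow(strategy_codes) != S) stop("'strategy_codes' must have one row per strategy")
  }
  if (!is.null(effect_sizes)) {
    effect_sizes <- as.matrix(effect_sizes)
    if (!all(dim(effect_sizes) == c(S, K))) {
      stop("'effect_sizes' must match the dimensions of 'discr_values'")
    }
  }
  structure(list(discr_values = discr_values, weights = weights,
                 strategy_codes = strategy_codes, effect_sizes = effect_sizes),
            class = "strategy_panel")
}

#' @export
print.strategy_panel <- function(x, ...) {
  cat(sprintf("Strategy panel: %d strategies x %d datasets\n",
              nrow(x$discr_values), ncol(x$discr_values)))
  if (!is.null(x$strategy_codes)) {
    cat(sprintf("  %d analysis stage(s): %s\n", ncol(x$strategy_codes),
                paste(names(x$strategy_codes), collapse = ", ")))
  }
  if (!is.null(x$effect_sizes)) cat("  effect sizes present\n")
  invisible(x)
}

mean_discr <- function(panel) {
  drop(panel$discr_values %*% panel$weights)
}

#' Rank strategies against the most replicable one
#'
#' Computes each strategy's weighted mean replicability, identifies the best
#' strategy (argmax), and tests every other strategy against it with the
#' two-sample comparison test run per dataset on the underlying measurement
#' sets; per-dataset p-values are pooled across datasets with Fisher's
#' method. The best strategy's p-value is reported as 1 by convention, and
#' the output is ordered by p-value (best first).
#'
#' @param panel a [strategy_panel()].
#' @param data nested list: `data[[strategy]][[dataset]]` is the
#'   [measurement_set()] that produced the corresponding panel cell.
#' @param n_perm permutations per two-sample test.
#' @param seed integer seed.
#' @return data.frame with `strategy`, `mean_discr`, `p_value`, ordered with
#'   the best strategy first.
#' @export
rank_strategies <- function(panel, data, n_perm = 500L, seed = 1L) {
  stopifnot(inherits(panel, "strategy_panel"))
  S <- nrow(panel$discr_values); K <- ncol(panel$discr_values)
  if (S < 2L) stop("ranking needs at least two strategies")
  if (length(data) != S || any(vapply(data, length, integer(1)) != K)) {
    stop("'data' must be a list of S strategies, each a list of K measurement sets")
  }
  md <- mean_discr(panel)
  best <- which.max(md)
  p <- rep(1, S)
  for (s in seq_len(S)) {
    if (s == best) next
    pk <- vapply(seq_len(K), function(k) {
      test_two_sample(data[[best]][[k]], data[[s]][[k]], stat = "discr",
                      n_perm = n_perm, seed = seed + 1000L * s + k)$p_value
    }, numeric(1))
    # Fisher combination across datasets
    X2 <- -2 * sum(log(pk))
    p[s] <- stats::pchisq(X2, df = 2 * K, lower.tail = FALSE)
  }
  out <- data.frame(strategy = rownames(panel$discr_values),
                    mean_discr = md, p_value = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_value, -out$mean_discr, decreasing = TRUE), , drop = FALSE]
}

#' Per-stage attribution of replicability differences
#'
#' For each analysis stage, ranks the stage's options by the mean
#' replicability of the strategies using them, then pairs every strategy
#' using the best option with its counterpart using the runner-up option
#' and all other stages held fixed. A one-sided Wilcoxon signed-rank test on
#' the paired mean-replicability differences asks whether the best option
#' beats the runner-up; p-values are Bonferroni-corrected across stages.
#'
#' @param panel a [strategy_panel()] with `strategy_codes`.
#' @return data.frame with one row per stage: `stage`, `best`, `runner_up`,
#'   `n_pairs`, `mean_diff`, `p_value`, `p_adjusted`.
#' @export
one_factor_analysis <- function(panel) {
  stopifnot(inherits(panel, "strategy_panel"))
  codes <- panel$strategy_codes
  if (is.null(codes)) stop("panel has no strategy_codes")
  md <- mean_discr(panel)
  stages <- names(codes)
  out <- lapply(stages, function(stage) {
    opt <- as.character(codes[[stage]])
    levs <- unique(opt)
    by_opt <- vapply(levs, function(l) mean(md[opt == l]), numeric(1))
    ord <- order(by_opt, decreasing = TRUE)
    best <- levs[ord[1]]
    runner <- if (length(levs) >= 2L) levs[ord[2]] else best
    if (best == runner || length(levs) < 2L) {
      return(data.frame(stage = stage, best = best, runner_up = runner,
                        n_pairs = 0L, mean_diff = 0, p_value = 1))
    }
    other <- do.call(paste, c(codes[setdiff(stages, stage)], sep = "\r"))
    ib <- which(opt == best)
    ir <- which(opt == runner)
    m <- match(other[ib], other[ir])
    keep <- !is.na(m)
    if (!any(keep)) stop("no matched strategy pairs for stage '", stage, "'")
    diffs <- md[ib[keep]] - md[ir[m[keep]]]
    p <- if (all(diffs == 0)) 1 else {
      suppressWarnings(stats::wilcox.test(diffs, alternative = "greater")$p.value)
    }
    data.frame(stage = stage, best = best, runner_up = runner,
               n_pairs = sum(keep), mean_diff = mean(diffs), p_value = p)
  })
  out <- do.call(rbind, out)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "bonferroni")
  out
}

minmax <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(NULL) # degenerate, caller excludes the dataset
  (x - r[1]) / (r[2] - r[1])
}

#' Regression of downstream effect size on replicability
#'
#' Within each dataset, min-max normalizes the strategies' replicability
#' values and their downstream effect sizes to \[0, 1\], regresses the
#' normalized effect size on the normalized replicability (OLS), and tests
#' each slope with a robust Z-test (slope over its HC3
#' heteroskedasticity-consistent standard error against a standard normal).
#' The aggregate slope is the weighted mean over datasets using the panel
#' weights. Datasets with a constant replicability or effect-size column are
#' excluded and reported.
#'
#' @param panel a [strategy_panel()] with `effect_sizes`.
#' @param alpha significance level for counting significantly positive
#'   slopes.
#' @return list with `slopes` (per-dataset data.frame: `dataset`, `slope`,
#'   `se`, `z`, `p_value`), `aggregate_slope` (weighted mean),
#'   `frac_positive`, `frac_significant`, and `excluded` dataset names.
#' @export
effect_vs_replicability <- function(panel, alpha = 0.05) {
  stopifnot(inherits(panel, "strategy_panel"))
  if (is.null(panel$effect_sizes)) stop("panel has no effect_sizes")
  K <- ncol(panel$discr_values)
  rows <- list(); excluded <- character(); w_used <- numeric()
  for (k in seq_len(K)) {
    x <- minmax(panel$discr_values[, k])
    y <- minmax(panel$effect_sizes[, k])
    nm <- colnames(panel$discr_values)[k]
    if (is.null(x) || is.null(y)) {
      excluded <- c(excluded, nm)
      next
    }
    fit <- stats::lm(y ~ x)
    se <- sqrt(sandwich::vcovHC(fit, type = "HC3")[2, 2])
    b <- stats::coef(fit)[[2]]
    z <- b / se
    rows[[length(rows) + 1L]] <- data.frame(
      dataset = nm, slope = b, se = se, z = z,
      p_value = stats::pnorm(z, lower.tail = FALSE))
    w_used <- c(w_used, panel$weights[k])
  }
  if (!length(rows)) stop("no dataset with non-constant columns")
  slopes <- do.call(rbind, rows)
  w <- w_used / sum(w_used)
  list(slopes = slopes,
       aggregate_slope = sum(w * slopes$slope),
       frac_positive = mean(slopes$slope > 0),
       frac_significant = mean(slopes$p_value <= alpha),
       excluded = excluded)
}
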