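---
title: "Discriminability as a replicability statistic: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminability as a replicability statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discriminability)
```

## The problem

Test-retest designs measure each item — a participant, a biological sample, a
specimen — several times under nominally fixed conditions. Good measurements
place repeats of the same item close together relative to measurements of
other items; accidental deviations (scanner drift, batch effects, measurement
noise) push them apart. A replicability statistic should quantify exactly this
contrast, for multivariate and non-Gaussian data, and should be usable to
*choose between* acquisition and analysis strategies rather than only to
audit a dataset after the fact.

## The Discr statistic

Let item $i$ have $s_i \ge 2$ measurements, $N = \sum_i s_i$ in total, and let
$D$ be the matrix of pairwise dissimilarities (Euclidean by default; any
registered dissimilarity is accepted). For every ordered within-item pair
$(j, j')$ and every measurement $k$ of a different item, a *violation* occurs
when $D(j,k) < D(j,j')$; an exact tie counts one half. The per-measurement
discriminability of $j$ is the fraction of its comparisons that are not
violated, and Discr is the mean of the per-measurement values over all
measurements belonging to items with replicates.

In the balanced two-replicate, tie-free case this is exactly
$$\mathrm{Discr} \;=\; 1 - \frac{f}{N(N-1) - g},$$
with $f$ the violation count and $g = 2n$ the number of ordered within-item
pairs. Perfectly discriminable data attain 1; exchangeable data (no
item-specific information) sit at $1/2$ in expectation. Because only the
*ranks* of distances enter, the statistic is invariant to strictly increasing
transforms of the dissimilarities, and in particular to rigid motions and
monotone rescalings of Euclidean features.

Three choices in the estimator deserve a note:

* **Ties count one half.** The tie-free definition needs no convention;
  half-weighting extends it continuously, keeps the no-ties case exact, and
  makes the statistic well defined on lattice-valued or heavily rounded
  data.
* **General replicate counts.** With $s_i > 2$ every ordered within-item
  pair is compared against all across-item measurements, and measurements
  are aggregated by first averaging within each anchor measurement. When
  all $s_i$ are equal this coincides with averaging over pairs, and for
  $s_i \equiv 2$ with the closed form above.
* **Singleton items.** An item measured once has no within-item pair; it is
  excluded from the statistic with a warning and reported in the fitted
  object rather than raising an error, since real panels routinely contain
  such items.

The implementation sorts, per anchor measurement, the across-item distances
once and locates each within-item distance by binary search, so the cost is
$O(N^2 \log N)$ independent of the replicate counts; the inner loop is
compiled (Rcpp). The test suite checks exact equality against a naive
triple-loop oracle on hundreds of random instances, with and without
engineered ties.

## Hypothesis tests

**One-sample (is the dataset discriminable at all?).** $H_0: R = R_0$ versus
$H_A: R > R_0$, where $R_0$ is the replicability of equally sized data with
no item-specific information. The null is simulated by uniformly permuting
the item labels over measurements, which preserves the multiset of replicate
counts. The p-value uses the add-one formula
$(1 + \#\{R^{(b)} \ge R\})/(1 + B)$, so it is never zero and the test is
valid (level at most $\alpha$, up to the discreteness of $B$ permutations)
at any $B$.

**Two-sample (is strategy 1 more discriminable than strategy 2?).**
$H_0: R^{(1)} = R^{(2)}$ versus $H_A: R^{(1)} > R^{(2)}$, for two strategies
applied to the same items with the same replicate counts. The observed
statistic is $R^{(1)} - R^{(2)}$; null draws swap, independently per item
with probability $1/2$, the item's whole block of measurements between the
strategies. The block swap preserves within-strategy dependence and enforces
exchangeability of the strategy labels, which is the natural null for paired
strategies. A pooled relabelling (ignoring the pairing) would also be
conceivable; we prefer the block swap because it conditions on the items
actually observed. Features are stacked and one distance (and, for the
kernel statistic, one Gram) matrix is computed up front, with the kernel
bandwidth fixed *before* permuting — recomputing it per permutation would
change the null hypothesis being simulated. Each permutation is then a
row-subset evaluation, and swapped rows keep their original positions so
that identical inputs produce a bit-identical degenerate null.

Both tests pre-draw their permutation streams from the seed, so results are
reproducible and independent of evaluation order. Any of the package's
statistics (`discr`, `icc`, `picc`, `i2c2`, `fingerprint`, `kernel`) can be
plugged into either test; statistics needing features (ICC, PICC, I2C2)
cannot be run from a distance matrix alone.

## Comparator statistics

The comparators use their canonical published forms:

* **ICC**: one-way random-effects ANOVA estimator
  $(MS_B - MS_W)/(MS_B + (k_0 - 1)MS_W)$ with the standard $k_0$ correction
  for unbalanced designs. It can be negative when within-item scatter
  exceeds between-item scatter.
* **PICC**: ICC of the scores on the first principal component
  (column-centered, unscaled PCA).
* **I2C2**: under $W_{ij} = \mu + X_i + U_{ij}$, the trace ratio
  $tr(\Sigma_X)/(tr(\Sigma_X)+tr(\Sigma_U))$ with moment estimators:
  $tr(\hat\Sigma_U)$ is the mean of $\tfrac12\|W_{ij}-W_{ij'}\|^2$ over
  within-item pairs and $tr(\hat\Sigma_X)$ the total trace minus that,
  floored at zero and the ratio truncated to $[0,1]$. This is a
  simplification of the original hierarchical-shrinkage fit; it has the same
  population target and is transparent enough to verify by parameter
  recovery.
* **Fingerprint index**: fraction of items identified by nearest-neighbour
  matching between sessions 1 and 2, averaged over the two directions; ties
  resolve to a mismatch (conservative). When sessions are unlabeled, each
  item's first two measurements act as the two sessions; additional sessions
  are ignored.
* **Kernel**: the unbiased squared MMD averaged over all pairs of items with
  replicates, Gaussian kernel, bandwidth = median of pooled pairwise
  distances. The unbiased estimator can be negative; the reported value is
  floored at 0 with the raw value kept in the details.
* **DCorr**: bias-corrected (U-centered) distance correlation, used as the
  downstream effect-size measure; categorical covariates are one-hot
  encoded.

## Synthetic benchmarks

The univariate panel (`sim_1d`) is deterministic — ten items at centers
$1,\dots,10$ measured at center $\pm 0.1$ — so the qualitative contrasts are
exact rather than stochastic:

* *discriminable*: Discr is exactly 1 and all statistics are high.
* *offset*: every second measurement is displaced by $1.2$ (1.2 times the
  center spacing), past the neighbouring item's first measurement. Discr
  drops moderately ($0.806$) while nearest-neighbour identification
  collapses (fingerprint $0.1$); ICC barely moves since item means retain
  their spacing.
* *outlier*: two items carry an outlier second measurement, item 1 displaced
  by $-1.5$ and item 2 by $+40$. Only 4 of 20 measurements are affected, so
  Discr stays high ($0.903$), but the outliers inflate the within-item mean
  square past the between-item mean square and ICC is negative ($-0.076$).
  The displacement pattern matters: two large displacements in *opposite*
  directions inflate the between-item variance as fast as the within-item
  variance and leave ICC positive; the same-direction, unequal-magnitude
  pattern used here is the regime in which ICC's sign actually flips while
  most measurements remain perfectly discriminable.

The two-dimensional settings (`sim_2d`, 128 measurements each) probe the
statistics' behaviour as within-item (accidental) variance grows. A single
`noise_scale` knob multiplies the within-item noise sd: `gaussian` (16
spherical Gaussians on a unit grid, noise sd $0.2 \times$ scale; items split
into two classes of 8 by alternating grid assignment), `cross` (two items,
same mean, sd $(1, \sqrt{0.05})$ versus the transpose, plus isotropic noise),
`ball_circle` (uniform unit ball versus unit circle plus noise), `xor`
(two-component mixtures with means in XOR arrangement), and `no_signal`
(identical Gaussians; population Discr $1/2$). For the two-item settings the
class label equals the item label. `bayes_accuracy` evaluates the optimal
classifier under the true generative densities — closed-form Gaussian
mixtures where available, and fixed low-discrepancy quadrature for the
ball/circle densities — providing the downstream-performance ceiling against
which replicability statistics are compared.

Two caveats on what these generators do and do not show. They emulate
*item-level heterogeneity plus isotropic accidental noise* in low dimension;
they do not emulate high-dimensional feature spaces, structured artefacts
(motion, batch), session effects, or non-exchangeable noise, so passing the
benchmark suite demonstrates correctness of the statistics and validity of
the tests, not performance on any particular real modality. And the `xor`
setting is deliberately adversarial: at very small noise its within-item
mixture separation exceeds the across-item separation and Discr sits below
$1/2$, with the one-sample test (one-sided, greater) powerless; signal
emerges at moderate noise. The default sweep grid (`noise_scale` from 1 to
5.5 in ten steps) therefore starts where all four signal settings carry
detectable structure, and "low noise" in the power summaries refers to the
low end of that grid.

## Problem sizes used by the shipped checks

The test suite and reproduction script use: 200 random instances
($n \le 8$, $s_i \le 4$, $d \le 3$) for oracle equivalence; 500 independent
datasets with 200 permutations each for the size (validity) checks of both
tests; 500 Monte-Carlo iterations with 100 permutations for the power
summaries; a 10-point noise grid with 100 replicates per point for the
monotonicity and Bayes-tracking checks; and $10^5$ Monte-Carlo draws per
grid point for the Bayes oracle. These sizes put the Monte-Carlo error well
inside the asserted margins.

## Strategy selection

`rank_strategies` orders strategies by weighted mean Discr across datasets —
weights default to dataset sizes, normalized — and tests each strategy
against the argmax with the two-sample comparison run per dataset, pooling
per-dataset p-values by Fisher's method ($-2\sum\log p_k \sim \chi^2_{2K}$
under the null). The best strategy's p-value is 1 by convention.

`one_factor_analysis` attributes replicability differences to individual
analysis stages: within each stage it pairs every strategy using the
best-performing option with its counterpart under the runner-up option,
holding all other stages fixed, and applies a one-sided Wilcoxon signed-rank
test to the paired differences, Bonferroni-corrected across stages. Because
the best option is chosen from the same data being tested, the selected
p-values are not exactly uniform under a global null (they are stochastically
smaller — a selection effect inherent to best-versus-runner-up designs); the
shipped checks therefore verify the practically relevant guarantee that
strong flags ($p \le 0.001$ after correction) are rare when no stage
matters, rather than exact uniformity.

`effect_vs_replicability` regresses min-max-normalized downstream effect
sizes (DCorr against a covariate) on normalized replicability within each
dataset, tests each OLS slope with a robust Z statistic (slope over its HC3
heteroskedasticity-consistent standard error against a standard normal), and
aggregates slopes by the panel weights. Datasets with a constant column are
excluded and reported; the normalization makes slopes comparable across
datasets but also means a planted generative slope must be interpreted on
the normalized scale.

## Known limitations

* Discr saturates at 1: strategies that are all perfectly discriminable
  cannot be distinguished without sharpening the comparison (e.g. shifting
  or scaling the across-item distances), which this package does not do.
* High replicability is necessary, not sufficient, for scientific utility;
  a perfectly discriminable measurement can be biologically meaningless.
* The $O(N^2)$ distance matrix limits practical use to $N$ up to roughly
  $10^4$ measurements; no subsampled approximation is provided.
* The two-sample test requires feature input (paired measurement sets);
  it cannot run from two separate distance matrices because the block-swap
  null needs cross-strategy distances.
* Within/between-class decompositions of discriminability are not
  implemented.
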