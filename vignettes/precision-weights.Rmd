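---
title: "Precision weights for spatially variable gene detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precision weights for spatially variable gene detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotweights)
```

## The problem

Spatially resolved transcriptomics (SRT) assays such as 10x Visium measure
UMI counts $r_{gi}$ for genes $g = 1,\dots,G$ at spatial locations
$s_i$, $i = 1,\dots,n$. A standard analysis transforms counts to logCPM,

$$y_{gi} = \log_2\!\left(\frac{r_{gi} + 0.5}{R_i + 1} \times 10^6\right),
\qquad R_i = \sum_g r_{gi},$$

and ranks genes as *spatially variable* (SVGs) with a Gaussian-process
(GP) model per gene. Count noise on the log scale is not homoskedastic:
lowly expressed genes carry systematically larger residual variance. This
mean–variance relationship leaks into SVG rankings — the GP's non-spatial
variance component absorbs the extra noise, deflating the spatial effect
size for low-expression genes — so rankings end up tracking mean
expression rather than spatial signal (the *mean–rank* relationship).

spotweights estimates observation- and gene-level precision weights from
the gene-wise mean–variance trend, in the spirit of limma-voom, and
applies them to the GP likelihood-ratio ranking via delta-method
rescaling.

## The model

Per gene, expression follows a GP regression with exponential covariance:

$$y \sim \mathcal N\!\big(X\beta,\; \Sigma\big), \qquad
\Sigma = \sigma^2 C(l) + \tau^2 I, \qquad
C_{ij}(l) = \exp\!\big(-\|s_i - s_j\| / l\big),$$

with spatial variance $\sigma^2$, nugget (non-spatial noise) $\tau^2$ and
lengthscale $l$. The effect size is the proportion of spatial variance
$\hat\sigma^2 / (\hat\sigma^2 + \hat\tau^2)$, and the test statistic is
the likelihood ratio against the linear model with $\sigma^2 = 0$
(two extra parameters; p-values use a $\chi^2_2$ reference, which is
conservative because the null places $\sigma^2$ on the boundary — ranking
by the LR statistic itself is the primary output, and the p-value column
is secondary).

Fitting a dense GP per gene is $O(n^3)$; we use a nearest-neighbor GP
(NNGP / Vecchia) approximation: observations are put in a fixed
conditioning order (lexicographic in $x$, then $y$) and each conditions
only on its $m$ nearest predecessors ($m = 15$ by default, the
conventional choice at Visium scale). The nugget is added to every
conditional variance (a "response-level" NNGP), so with $m = n - 1$ the
approximation equals the dense likelihood exactly — a property the test
suite asserts to $10^{-8}$. The factor construction is compiled code
(RcppArmadillo), as in the GP packages this follows.

Two numerical choices matter:

* $\beta$ is profiled analytically by generalized least squares inside
  every likelihood evaluation, never searched numerically.
* The total variance $v = \sigma^2 + \tau^2$ is also profiled in closed
  form: writing $\Sigma = v\,(sC + (1-s)I)$ with spatial proportion
  $s$, the profiled ML of $v$ is RSS$/n$ on the whitened data. The
  numeric search therefore runs over only $(\mathrm{logit}\, s, \log l)$,
  by L-BFGS-B from three deterministic starts — an even $\sigma^2/\tau^2$
  split with $l$ at 5%, 15% and 50% of the maximum coordinate extent —
  keeping the best final likelihood (ties to the first start). This is
  the same maximum-likelihood problem as a three-parameter search over
  $(\log\sigma^2, \log\tau^2, \log l)$ with one dimension solved exactly;
  it cuts likelihood evaluations by roughly an order of magnitude and
  removes the ridge along which $\sigma^2$ and $\tau^2$ trade off against
  a shared scale. Variance estimates below $10^{-6}$ times the sample
  variance are reported as exactly zero (boundary estimates are expected
  under the null); constant genes short-circuit to the null fit with
  LR $= 0$.

## The weights

1. **Per-gene fits.** An intercept-only NNGP fit per gene gives the
   marginal mean $x_i^\top\hat\beta_g$ (a constant per gene). The
   residual standard deviation around that constant,
   $s_g = \sqrt{\sum_i (y_{gi} - x_i^\top\hat\beta_g)^2 / (n-1)}$, is the
   gene's total scatter and the trend's response.
2. **Trend.** $\sqrt{s_g}$ (square roots of standard deviations are
   roughly symmetric, the voom convention) is regressed on the *average
   logcount* $\tilde r_g = \bar y_g + \log_2 \tilde R - \log_2 10^6$,
   where $\tilde R = \exp\{\tfrac1n \sum_i \log R_i\}$ is the geometric
   mean library size (used instead of a product, which overflows). The
   regression is a penalized cubic smoothing spline. Smoothing is
   selected by REML (`mgcv::gam`, shrinkage basis) rather than GCV:
   trend-prediction error is raised to the fourth power on its way to
   becoming a weight, and GCV's known tendency to undersmooth — we
   measured ~3.5 effective df fitted to data whose true trend was flat —
   turns harmless wiggles into 30% weight swings, while REML shrinks a
   flat trend to ~1 df. `fit_trend(method = "gcv")` keeps the
   alternative. Genes with near-zero residual sd (constant expression)
   are excluded from fitting — they would pin the spline at zero — but
   still receive predictions, and predictions are floored at $10^{-3}$
   times the median response so a spline zero-crossing can never make a
   weight infinite.
3. **Weights.** Each observation's fitted value maps to the count scale,
   $\hat\lambda_{gi} = \hat\mu_{gi} + \log_2(R_i + 1) - \log_2 10^6$
   (exactly $\log_2(r + 0.5)$ when $\hat\mu$ is the logCPM of count
   $r$). Values outside the trend's fitted domain are evaluated at the
   nearer boundary — the trend is never extrapolated. The weight is
   $w_{gi} = \mathrm{spl}(\hat\lambda_{gi})^{-4}$: the fourth power
   undoes the square root and squares the standard deviation, so $w$ is
   an inverse predicted variance.

Which fitted value $\hat\mu_{gi}$ enters step 3 decides whether the
weights do anything observation-level, so the default deserves a note.
With the constant marginal mean, $\hat\lambda_{gi}$ varies within a gene
only through $R_i$, and a weight vector that is constant within a gene
provably leaves the weighted likelihood-ratio statistic unchanged (the
test suite asserts this invariance) — on data whose library sizes barely
vary, weighting would be a no-op. The default therefore evaluates the
trend at each observation's *fitted value from the model*: the
empirical-Bayes posterior mean of the gene's expression surface,
$x_i^\top\hat\beta_g + f_g\,\hat\sigma^2 C (\hat\sigma^2 C +
\hat\tau^2 I)^{-1}(y_g - X\hat\beta_g)$, shrunk by the positive-part
evidence factor $f_g = \max(0, 1 - 2/LR_g)$. The shrinkage constant is
the $\chi^2_2$ null mean of the LR statistic, so a gene whose apparent
spatial structure is indistinguishable from noise keeps a flat fitted
value and constant weights — without it, borderline null genes feed
their own smoothed noise back into their weights and can ride the
feedback to the top of the weighted ranking. For a clearly spatial gene
$f_g \approx 1$ and $\hat\lambda$ tracks the local expression level, so
regions the gene barely reaches — where log-scale count noise is
largest — are downweighted within that gene. Note the asymmetry with
step 1: the trend's *response* stays anchored to the marginal residuals
(stable, independent of per-gene kriging noise); only the *lookup point*
is observation-level. `spatial_weights(fitted = "marginal")` keeps the
constant-mean alternative.

To use the weights in a fitter that knows nothing about them, data and
design are rescaled (the delta-method device): $y^* = W y$, $X^* = W X$
with $W = \mathrm{diag}(w_g)$. With an intercept-only design, $X^*$ *is*
the weight vector, and no new intercept is added. The weighted LR
compares the GP fit on $(y^*, X^*)$ against the weighted linear model on
the same transformed data, so the ratio isolates the spatial variance
under identical weighting. Ties in every ranking break by first
occurrence in the input gene order.

## The simulator

`simulate_counts()` draws Poisson counts with a log-Gaussian intensity:

$$c_{gi} \sim \mathrm{Poisson}(\lambda_{gi}), \qquad
\log \lambda_{gi} = \beta_g + \eta_{gi}, \qquad
\eta_g \sim \mathcal N(0, \sigma_g^2 K),$$

with $K$ the exponential kernel on a lengthscale shared by all genes in a
run (so a single Cholesky factor is reused). Per gene,
$\beta_g \sim U(\ln 0.5, \ln 1)$ and $\sigma^2_g \sim U(0.2, 1)$, drawn
independently so spatial signal appears at every mean-expression level; a
fraction `prop_null` (default 0.5) of genes get $\sigma^2 = 0$. True
negatives are required for FDR/TNR/TPR evaluation, which is why the null
fraction exists as an explicit parameter rather than every gene carrying
positive spatial variance. A squared-exponential kernel is available as a
sensitivity switch, but the exponential kernel is the default since it
matches the model being evaluated.

The default spot layout is an isotropic hexagonal lattice of 44 offset
rows × 22 spots = 968 spots with unit pitch (one coordinate unit = one
inter-spot distance, 100 µm on a physical Visium array), emulating a
Visium capture-area subset. The default lengthscale is 2% of the maximum
axis extent ("scaled lengthscale 0.02"), giving nearest-neighbor
correlation $e^{-1/0.745} \approx 0.26$ — short-range spatial structure,
the regime where mean-variance bias matters most. What the simulator does
*not* emulate: library-size variation driven by capture efficiency (its
$R_i$ are sums of independent Poisson draws, so they vary only a few
percent, whereas real spots vary several-fold), dropout beyond Poisson
zeros, negative-binomial overdispersion, and multi-lengthscale mixtures.
Passing tests on simulated data therefore demonstrate correctness of the
machinery and behavior under the stated generative model, not performance
under every artifact of real tissue.

## Evaluation

`decile_rank_summary()` bins genes into deciles of mean logcounts
(decile 1 = lowest; quantile bins, boundary genes to the lower decile)
and counts how many of the global top 10% of ranks fall in each decile.
`bias_score()` scalarizes this as the $\chi^2$ divergence of the signal
counts from a uniform spread — 0 means the top-ranked genes ignore mean
expression entirely. `error_rate_curves()` computes FDR
($FP/\max(1, FP+TP)$, so an empty rejection set has FDR 0), TNR and TPR,
either at BH-adjusted p-value thresholds (default) or at top-$k$ rank
cutoffs, and `aggregate_over_seeds()` averages curves pointwise across
simulation seeds. `run_svg_benchmark()` chains
simulate → weights → rank (both ways) → evaluate; the intercept-only fits
from the weight stage double as the unweighted ranking, so a seed costs
two fit passes.

## Problem sizes and design choices in the checks

The package's own end-to-end checks run the benchmark at 300 genes on a
406-spot lattice (29 × 14, same unit pitch) for 5 seeds, with the
simulation lengthscale kept at the default grid's value (0.745 pitch
units). Keeping the kernel fixed while scaling down the spot count
mirrors how the scaled-lengthscale convention is anchored to the tissue
area rather than to whichever subset of spots is analyzed; shrinking the
kernel with the subset would silently change the estimand (per-spot
correlation would drop from 0.26 to 0.13 and detection power would
collapse). Variance-component recovery is checked at $n = 400$,
$\sigma^2 = 1$, $\tau^2 = 0.5$, scaled lengthscale 0.1, where the median
estimated proportion of spatial variance must land within ±0.15 of the
true 2/3.

## Known limitations

* The $\chi^2_2$ p-value is conservative under the boundary null for the
  unweighted fit; ranks are the primary output. For the *weighted* fit
  the data-dependent weights additionally perturb calibration: on
  simulated data the weighted ranking rejects more genes at a given
  BH threshold (higher power) with a mildly inflated false discovery
  rate (around 0.07–0.09 at nominal 0.05, versus near 0 unweighted),
  while at a matched rejection-set size the two rankings recover true
  spatially variable genes at nearly the same rate. Weighted p-values
  should be treated as scores, not calibrated probabilities.
* Under `fitted = "marginal"`, observation-level weight variation enters
  only through library sizes; in data whose library sizes barely vary
  (including this simulator's output) that makes weighting a near-no-op.
  The smoothed default avoids this, at the cost of one dense
  $n \times n$ solve per spatially variable gene.
* Gene filters default to the conventional Visium thresholds (≥ 2 counts
  in ≥ 0.2% of spots, or a total-UMI floor for sparse tissues); library
  sizes are by default *not* recomputed after filtering, so CPM
  denominators keep reflecting total capture.
* No anisotropic kernels, no multi-sample fitting, no uncertainty
  quantification on variance components.

## A worked example

```{r example, eval = FALSE}
library(spotweights)

sim <- simulate_counts(n_genes = 200,
                       grid = make_grid("hex", n_rows = 22, n_cols = 11),
                       seed = 1)
sw <- spatial_weights(sim$data)
autoplot(sw)                       # mean-variance trend

expr <- compute_logcpm(sim$data)
unweighted <- rank_svgs_unweighted(sim$data, expr, fits = sw$fits)
weighted <- rank_svgs_weighted(sim$data, expr, weights = sw$weights)

mean_lc <- colMeans(lognorm_counts(sim$data)$values)
bias_score(decile_rank_summary(unweighted, mean_lc))
bias_score(decile_rank_summary(weighted, mean_lc))
```
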