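---
title: "Kernel equating and data-driven bandwidth selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel equating and data-driven bandwidth selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kebandwidth)
```

## The problem

Scores from two forms of a standardized test are not interchangeable:
forms differ slightly in difficulty, and the groups taking them differ in
ability. Observed-score equating replaces a score $x$ on form X by the
form-Y score with the same cumulative probability in a common target
population,

$$\varphi_Y(x) = G_Y^{-1}(F_X(x)),$$

the equipercentile transformation. Test scores are discrete, so $F_X$ and
$G_Y$ are step functions and the composition above is not well defined.
Kernel equating resolves this by *continuization*: the discrete score
variable $X$ with probabilities $r_j$ at scores $x_j$ is replaced by

$$X(h) = a(X + hZ) + (1 - a)\mu, \qquad
  a^2 = \frac{\sigma^2}{\sigma^2 + h^2},$$

with $Z$ standard normal. The shrinkage factor $a$ makes the first two
moments of $X(h)$ equal $\mu$ and $\sigma^2$ exactly for every bandwidth
$h$, so continuization never distorts the location or scale of the score
distribution. The resulting CDF is a Gaussian mixture,

$$F_h(x) = \sum_j r_j \,\Phi\!\left(\frac{x - a x_j - (1-a)\mu}{a h}\right),$$

strictly increasing for every $h > 0$, hence invertible. Small $h$ tracks
the discrete masses; large $h$ converges to the normal CDF with the same
mean and variance, so the equating function converges to the classical
linear transformation $\mu_Y + (\sigma_Y/\sigma_X)(x - \mu_X)$. At
$h \approx 0.33$ the kernel estimator closely approximates traditional
percentile-rank equipercentile equating with linear interpolation. Both
limits are exercised in the test suite.

## Pipeline

`kebandwidth` implements the full observed-score pipeline:

1. **Presmoothing** (`fit_loglinear_univariate()`,
   `fit_loglinear_bivariate()`, `select_model()`): Poisson log-linear
   models with polynomial score terms. By the score equations of the
   exponential family, a degree-$T$ fit reproduces the observed moments of
   orders $1..T$ exactly, and fitted probabilities are strictly positive,
   which post-stratification requires. AIC is the customary selection
   criterion for univariate smoothing, BIC for bivariate NEAT smoothing;
   `select_model()` searches degrees 2–6 (univariate) or marginal degrees
   2–4 crossed with cross-moment sets $\{\}, \{(1,1)\},
   \{(1,1),(1,2),(2,1)\}, \{(1,1),(2,2)\}$ (bivariate).
2. **Design function** (`design_function()`): identity for equivalent
   groups (EG); for non-equivalent groups with an anchor test (NEAT),
   post-stratification reweights each population's conditional score
   distribution given the anchor by the target-population anchor
   distribution $w\,\Pr(A\mid P) + (1-w)\Pr(A\mid Q)$, default $w = 0.5$.
3. **Continuization and equating** (`continuize()`, `ke_equate()`).
4. **Evaluation** (`see_analytical()`, `see_bootstrap()`, `pre_moments()`,
   `mse_of_mean()`, `se_per_score()`, `dtm_compare()`).

## The six bandwidth selectors

All selectors operate on the presmoothed score probabilities (the
standard pipeline order); only LiCV goes back to the raw counts because
it resamples individual test takers.

* **Penalty** (`select_penalty()`): minimizes
  $\sum_j (\hat r_j - \hat f_h(x_j))^2 + \kappa \sum_j A_j$. The
  squared-distance term explodes as $h \to 0$ (the density at a score
  point behaves like $\hat r_j\,\phi(0)/h$) and grows slowly with
  oversmoothing bias, giving a well-defined interior minimum. $A_j$ flags
  score points near which the density slope flips sign. The package's
  default flags only *valleys* (slope negative at $x_j - w$, positive at
  $x_j + w$): an undersmoothed estimate develops a U-shape between
  adjacent score masses, whereas a genuine mode is not a smoothing
  defect. The alternative `direction = "both"` also flags modes; because
  any unimodal density then incurs a penalty whenever its mode falls
  within $w$ of a score point, the integer penalty (with the default
  $\kappa = 1$) dominates the $\sim 10^{-5}$-scale squared term and
  pushes the minimizer toward the normal limit — a behavior inconsistent
  with how this selector is reported to behave, which is why "valley" is
  the default. Defaults $\kappa = 1$, $w = 0.25$.
* **SRT** (`select_srt()`): Silverman's normal-reference rule adapted to
  the continuization by equating the effective kernel scale $a\,h$ to
  $0.9\,\sigma n^{-1/5}$, giving the closed form
  $h = 9\sigma/\sqrt{100\,n^{2/5} - 81}$. Deterministic given
  $(\sigma, n)$; carries a normality assumption that test data usually
  violate.
* **DS** (`select_ds()`): double smoothing. A deliberately large pilot
  bandwidth $q$ (default $3 \times$ SRT, configurable) produces an
  oversmoothed density; its values at the score points, renormalized to
  sum to one, replace $\hat r$ as mixture weights for a second estimate
  $\hat f^*_h$ evaluated on the $2J-1$ grid of scores and midpoints. The
  criterion matches $\hat f^*_h$ to the observed $\hat r_j$ at score
  points and to the pilot density at midpoints. The renormalization keeps
  $\hat f^*_h$ a proper density so both target types are on the
  probability scale.
* **LiCV** (`select_licv()`): the test takers are split at random into
  halves ($\lceil n/2\rceil / \lfloor n/2\rfloor$ for odd $n$); the first
  half yields a kernel density whose Poisson likelihood is evaluated
  against the second half's frequencies over the grid
  $h \in \{0.01, 0.02, \ldots, 5\}$; the per-split maximizer is stored
  and the median over `n_repeats` splits (1000 by canonical definition;
  configurable) is returned. By default each first half is presmoothed
  with an IC-selected univariate log-linear model before the density is
  built, mirroring the pipeline order used everywhere else; raw
  subsample proportions are available via `presmooth = "none"`, and the
  choice moves the selected bandwidth substantially (raw proportions
  reward heavier smoothing because the likelihood must average away
  sampling noise).
* **LCV** (`select_lcv()`): leave-one-out cross-validation,
  $J^{-1}\sum_j (\hat r_j - \hat f_h^{-j}(x_j))^2$, where
  $\hat f^{-j}$ omits the $j$-th score point's mass (without
  renormalizing the remaining weights; $a$ and $\mu$ stay those of the
  full distribution).
* **PLCV** (`select_plcv()`): the LCV criterion plus
  $\kappa \sum_j A_j$; with $\kappa = 0$ it is exactly LCV.

### A structural caveat about LCV on presmoothed distributions

On a unit-spaced score grid the leave-one-out density at $x_j$ can never
exceed roughly $(1 - \phi(0)/h)\,\hat r_j$ plus smoothing bias: removing
the self-mass leaves a hole that only more smoothing can fill. The LCV
criterion is therefore flat for $h \lesssim 0.4$ (where the left-out
density is essentially zero) and decreases monotonically until
oversmoothing bias finally dominates, which for realistic score
distributions happens only at $h \approx 5$ or later; for near-normal
presmoothed distributions the criterion keeps improving all the way to
the normal limit and the minimizer sits at the upper end of the search
range. Honest global minimization of this criterion consequently selects
large bandwidths, close to (or beyond) SRT, and PLCV inherits the
behavior since the valley penalty vanishes in that smooth regime. Reports
of LCV selecting very small, nearly data-independent bandwidths around
$1/3$ are consistent with an optimizer terminating on the small-$h$
plateau of this same criterion, not with its global minimum; the package
does not emulate that behavior. Users wanting a small-bandwidth,
probability-tracking selector should use the penalty or DS methods.

### Optimization

Penalty, DS, LCV and PLCV are minimized on the log scale over
$[0.01, 30]$: golden-section/parabolic search (`stats::optimize`) on five
log-spaced subintervals followed by a local refinement around the best
point. The subdivision guards against the local minima that the integer
penalty can create. Agreement with an exhaustive 0.001-step grid search
is part of the test suite. The LiCV grid search is exhaustive by
construction.

## Standard errors of equating

`see_analytical()` implements the delta-method standard error
$\mathrm{SEE}(x) = \lVert \hat J_\varphi \hat J_{DF} C\rVert$ per score
point. The Jacobian of the equating function with respect to the score
probabilities is computed in closed form, including the terms arising
because $\mu$, $\sigma^2$ and $a$ are themselves functions of the
probability vector (a finite-difference cross-check is in the test
suite). The design-function Jacobian is the identity for EG and the
post-stratification differentials for NEAT. $C$ is a factor of the
asymptotic covariance of the presmoothed probabilities,
$CC^\top = M B (B^\top M B)^{-1} B^\top M / n$ with
$M = \mathrm{diag}(\pi) - \pi\pi^\top$, which reduces to the multinomial
covariance when the model is saturated (or when raw proportions are used).
Bandwidths are treated as known constants. `see_bootstrap()` re-runs the
entire pipeline — presmoothing, bandwidth selection, equating — on
multinomial resamples of the test takers, so bandwidth variability *is*
reflected there; analytical and bootstrap SEEs agree away from the score
range's tails, where density denominators are tiny and divergence is
expected. The bootstrap is implemented for the EG design; a NEAT
bootstrap would resample the bivariate tables analogously but is not
currently provided.

## The synthetic data generator

`generate_truth()` emulates realistic score data: a latent trait is drawn
from a Beta distribution — Beta(5,5) symmetric, Beta(5,2) negatively
skewed, Beta(2,5) positively skewed, or an equal mixture of Beta(25,15)
and Beta(15,25) for bimodal — and multiplied by the test length, then
rounded to the integer score grid $0..J-1$. Under NEAT, test and anchor
traits are linked by a Gaussian copula with correlation $\rho = 0.75$
(anchor tests are built to correlate strongly with the total score); the
bimodal mixture quantile is inverted numerically. Population Q's form
scores are shifted by five units after rounding and clamped to the grid
(the anchor, being the common instrument, is not shifted); the shift
direction follows the score axis as generated, and X-score summaries are
unaffected by it because only Q's anchor margin enters the
post-stratified X distribution. One sample of size $n$ is drawn, fitted
with the scenario's log-linear design, and the strictly positive fitted
probabilities become the simulation truth — so the truth lies exactly in
the presmoothing family, and replicate-level presmoothing with the same
design is correctly specified, isolating bandwidth effects from model
misspecification. This is the main idealization: real score distributions
are not exact log-linear laws, real anchor relations are not Gaussian
copulas, and passing simulations therefore demonstrate correctness of
the machinery under the stated data-generating process, not robustness to
presmoothing misspecification.

Fixed presmoothing designs per condition: EG preserves 2 moments
(symmetric) or 3 (skewed, bimodal); NEAT preserves 4 marginal moments
with cross-moments $(1,1),(2,2)$ for symmetric/negatively skewed shapes,
and 2 marginal moments with cross-moment $(1,1)$ for positively
skewed/bimodal. "First and second cross-moment" admits two readings;
`cross_variant = "all2"` switches to $(1,1),(1,2),(2,1)$.
`model_selection = "ic"` replaces the fixed designs with an AIC/BIC
search.

`run_scenario()` draws `G` multinomial replicates from the truth,
presmooths each with the truth's design, applies the design function,
selects bandwidths with each requested method, equates, and aggregates:
mean and variance of selected bandwidths, MSE of the equated mean
(squared bias of replicate means plus their $G-1$-divisor variance),
per-score SE, PRE of the first ten moments, and pairwise
difference-that-matters counts. The PRE summary is computed on the
replicate-mean equated curve against the truth's Y moments. The equated
mean uses the truth's target-population weights, so the MSE isolates
equating-function error. A master seed expands deterministically into the
truth seed and per-replicate seeds.

## Problem sizes and numerical choices

* Replication counts: the full design uses $G = 1000$; the package's
  shipped acceptance runs use $G = 200$ for the deterministic-criterion
  selectors and $G = 50{-}100$ with 50–100 split repeats for LiCV, with
  Monte-Carlo tolerances of three standard errors of the replicate mean.
* Inverse CDF: vectorized bisection on
  $[\min x - 10h - 10\sigma,\ \max x + 10h + 10\sigma]$ to $10^{-10}$ on
  the probability scale; safe because $F_h$ is strictly increasing.
* Probabilities are validated to sum to 1 within $10^{-8}$ and
  renormalized only for deviations below that; larger violations are
  errors. Degenerate distributions ($\sigma^2 = 0$, a single score
  point) are rejected rather than special-cased.
* Tail SEE values where the Y density falls below $10^{-12}$ trigger a
  warning and are floored, not dropped.
* Gaussian-mixture evaluation and the LiCV likelihood grid are compiled
  (Rcpp); tests verify them against plain-R term-by-term oracles.

## Known limitations

* The analytical SEE treats bandwidths as fixed; only the bootstrap
  captures selection variability. An analytical correction for the SRT
  rule's bandwidth variability is not implemented.
* Adaptive (per-point) bandwidths and non-Gaussian kernels are out of
  scope, as are chained equating and IRT-based observed-score equating.
* The LCV/PLCV global minimizers are large for smooth presmoothed
  distributions (see the caveat above); they are faithful to their
  criterion but not to small reported bandwidths obtained from it.
* In this generator, doubling the anchor length (20 to 40 items) at
  fixed latent correlation $\rho = 0.75$ changes the post-stratified MSE
  only marginally: with the anchor unshifted between populations the
  post-stratification weights are nearly equal and anchor resolution is
  mechanically irrelevant, and even with Q's anchor distribution shifted
  the information gain from finer anchor strata is negligible relative to
  the rounding noise. Claims of large anchor-length effects on MSE are
  sensitive to the single truth draw used per configuration.
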