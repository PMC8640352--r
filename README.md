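# kebandwidth

Kernel equating of discrete test-score distributions with six data-driven
bandwidth selection methods, for psychometricians and methodologists who
need to make scores from different test forms interchangeable and to
understand how much the smoothing step matters.

## The method

Observed-score equating maps a score $x$ on form X to the form-Y score
with the same cumulative probability, $\varphi_Y(x) = G_Y^{-1}(F_X(x))$.
Because test scores are discrete, kernel equating first *continuizes*
each score distribution: the score variable $X$ with probabilities $r_j$
becomes $X(h) = a(X + hZ) + (1-a)\mu$ with $Z$ standard normal and
$a^2 = \sigma^2/(\sigma^2 + h^2)$, which preserves the mean and variance
for every bandwidth $h$ and yields the strictly increasing CDF

$$F_h(x) = \sum_j r_j\,\Phi\!\left(\frac{x - a x_j - (1-a)\mu}{a h}\right).$$

The bandwidth governs everything between two classical extremes: as
$h \to \infty$ the equating function becomes the linear transformation,
and near $h = 0.33$ it approximates traditional equipercentile equating
with linear interpolation. The package implements the full pipeline —
log-linear presmoothing with AIC/BIC model selection, equivalent-groups
(EG) and NEAT post-stratification design functions, equating, analytical
(delta-method) and bootstrap standard errors of equating, percent
relative error of moments — and six bandwidth selectors:

| method | idea |
|---|---|
| `select_penalty()` | squared distance between $\hat r_j$ and the density at the scores, plus a sign-change penalty |
| `select_srt()` | Silverman's rule adjusted for the shrinkage factor: $h = 9\sigma/\sqrt{100 n^{2/5} - 81}$ |
| `select_ds()` | double smoothing against a large pilot bandwidth on a score-and-midpoint grid |
| `select_licv()` | repeated half-splits, Poisson likelihood of one half under the other's kernel density, median of grid maximizers |
| `select_lcv()` | leave-one-out cross-validation on the score points |
| `select_plcv()` | LCV plus the sign-change penalty |

A simulation engine (`ke_scenario()`, `generate_truth()`,
`run_scenario()`) generates score data from beta or beta-mixture latent
traits (Gaussian copula between test and anchor, $\rho = 0.75$), fits a
log-linear "truth", draws multinomial replicates, and compares the
selectors by MSE of the equated mean, per-score SE, and PRE of the first
ten moments.

## Worked example

Equate two equivalent-group forms of a 20-item test:

```r
library(kebandwidth)
set.seed(1)
p1 <- dnorm(0:20, 10.2, 3.8); p2 <- dnorm(0:20, 11.0, 3.5)
x <- score_dist(0:20, counts = as.numeric(rmultinom(1, 800, p1 / sum(p1))))
y <- score_dist(0:20, counts = as.numeric(rmultinom(1, 800, p2 / sum(p2))))

fx <- select_model(x, criterion = "aic")   # log-linear presmoothing
fy <- select_model(y, criterion = "aic")
r <- fitted_score_dist(fx); s <- fitted_score_dist(fy)

hx <- select_penalty(r)$h
hy <- select_penalty(s)$h
round(c(hx, hy), 3)
#> [1] 0.652 0.649

eq <- see_analytical(fx, fy, ke_design("eg"), hx, hy)
round(cbind(x = eq$x_scores, equated = eq$equated, see = eq$see)[9:13, ], 3)
#>       x equated   see
#> [1,]  8   8.950 0.194
#> [2,]  9   9.903 0.183
#> [3,] 10  10.856 0.179
#> [4,] 11  11.807 0.182
#> [5,] 12  12.758 0.191
```

A score of 10 on form X is worth about 10.86 on form Y (form Y ran
slightly easier in this draw), with a standard error near 0.18 raw-score
units mid-range.

```r
round(pre_moments(eq$equated, r$probs, s$scores, s$probs, 5), 3)
#> [1] 0.001 0.000 0.007 0.021 0.042
```

The percent relative errors show the equated scores reproducing the first
five moments of the Y distribution to within 0.05%.

A thin command-line wrapper ships in `inst/scripts/kebandwidth`
(subcommands `bandwidth` and `equate` over TSV/CSV frequency tables).

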