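# Log-linear presmoothing: moment matching, model selection, covariance.

test_that("univariate fit reproduces a generating log-linear law", {
  x <- 0:10
  eta <- -0.5 + 0.9 * x - 0.08 * x^2
  p <- exp(eta) / sum(exp(eta))
  counts <- round(1e8 * p)
  f <- fit_loglinear_univariate(counts, 2, scores = x)
  expect_equal(f$fitted_probs, counts / sum(counts), tolerance = 1e-6)
})

test_that("moment matching holds for every preserved order", {
  d <- toy5_counts()
  f <- fit_loglinear_univariate(d, 2)
  obs <- d$counts / sum(d$counts)
  expect_equal(sum(f$fitted_probs * d$scores), 2.0, tolerance = 1e-8)
  expect_equal(sum(f$fitted_probs * d$scores^2), 5.2, tolerance = 1e-7)
  expect_equal(sum(obs * d$scores^2), 5.2)  # the observed second moment
  # degree 1 on uniform counts matches the sample mean exactly
  u <- score_dist(0:6, counts = rep(3L, 7))
  f1 <- fit_loglinear_univariate(u, 1)
  expect_equal(sum(f1$fitted_probs * u$scores), 3, tolerance = 1e-9)
  # fitted probabilities strictly positive, sum to one
  expect_true(all(f$fitted_probs > 0))
  expect_equal(sum(f$fitted_probs), 1, tolerance = 1e-10)
})

test_that("bivariate fit matches marginal and cross moments", {
  set.seed(4)
  xg <- 0:6; ag <- 0:3
  lam <- exp(0.2 + 0.5 * rep(xg, 4) - 0.06 * rep(xg, 4)^2 +
               0.4 * rep(ag, each = 7) - 0.1 * rep(ag, each = 7)^2 +
               0.02 * rep(xg, 4) * rep(ag, each = 7))
  counts <- matrix(rpois(28, 40 * lam / mean(lam)), 7, 4)
  tab <- biv_table(xg, ag, counts = counts)
  f <- fit_loglinear_bivariate(tab, 2, 2, cross = list(c(1, 1)))
  obs <- counts / sum(counts)
  fitm <- f$fitted_matrix
  gx <- rep(xg, 4); ga <- rep(ag, each = 7)
  for (mom in list(gx, gx^2, ga, ga^2, gx * ga)) {
    expect_equal(sum(fitm * mom), sum(obs * mom), tolerance = 1e-6)
  }
  # independence: empty cross set fits the product of the margins
  ind <- outer(c(2, 5, 9, 5, 2, 1, 1), c(3, 6, 6, 3))
  tabi <- biv_table(xg, ag, counts = ind)
  fi <- fit_loglinear_bivariate(tabi, 2, 2, cross = list())
  rowm <- rowSums(fi$fitted_matrix); colm <- colSums(fi$fitted_matrix)
  expect_equal(fi$fitted_matrix, outer(rowm, colm), tolerance = 1e-6)
})

test_that("bivariate self-consistency: generating law is recovered", {
  xg <- 0:5; ag <- 0:3
  gx <- rep(xg, 4); ga <- rep(ag, each = 6)
  eta <- 0.6 * gx - 0.09 * gx^2 + 0.5 * ga - 0.12 * ga^2 + 0.05 * gx * ga
  p <- exp(eta) / sum(exp(eta))
  counts <- matrix(round(2e8 * p), 6, 4)
  tab <- biv_table(xg, ag, counts = counts)
  f <- fit_loglinear_bivariate(tab, 2, 2, cross = list(c(1, 1)))
  expect_equal(as.numeric(f$fitted_matrix),
               as.numeric(counts / sum(counts)), tolerance = 1e-6)
})

test_that("information-criterion selection picks the generating degree", {
  x <- 0:20
  eta <- 2 + 0.8 * x - 0.04 * x^2
  p <- exp(eta) / sum(exp(eta))
  set.seed(11)
  hits <- 0
  for (i in 1:50) {
    counts <- as.numeric(rmultinom(1, 3000, p))
    sel <- select_model(score_dist(x, counts = counts),
                        candidates = 2:5, criterion = "aic")
    if (sel$design$degree == 2) hits <- hits + 1
  }
  expect_gt(hits / 50, 0.7)
  # single candidate comes back unchanged
  d <- toy5_counts()
  one <- select_model(d, candidates = 3, criterion = "aic")
  expect_equal(one$design$degree, 3)
  # BIC never selects a larger model than AIC on the same data
  set.seed(12)
  counts <- as.numeric(rmultinom(1, 1000, p))
  da <- select_model(score_dist(x, counts = counts), 2:6, "aic")
  db <- select_model(score_dist(x, counts = counts), 2:6, "bic")
  expect_lte(db$k, da$k)
})

test_that("cov_factor reduces to the multinomial covariance when saturated", {
  d <- toy5_counts()
  f <- fit_loglinear_univariate(d, 4)  # saturated: 5 cells, 5 parameters
  CC <- tcrossprod(cov_factor(f))
  r <- f$fitted_probs
  expect_equal(CC, (diag(r) - outer(r, r)) / f$n, tolerance = 1e-10)
  # rows of CC' sum to zero (probabilities sum to a constant)
  f2 <- fit_loglinear_univariate(d, 2)
  expect_lt(max(abs(rowSums(tcrossprod(cov_factor(f2))))), 1e-10)
  # multinomial factor helper agrees with its definition
  Cm <- multinomial_cov_factor(r, f$n)
  expect_equal(tcrossprod(Cm), (diag(r) - outer(r, r)) / f$n,
               tolerance = 1e-12)
})

test_that("cov_factor matches a parametric bootstrap of the fitter", {
  x <- 0:8
  eta <- 1 + 0.9 * x - 0.09 * x^2
  p <- exp(eta) / sum(exp(eta))
  n <- 800
  truth_fit <- fit_loglinear_univariate(round(1e6 * p), 2, scores = x)
  # asymptotic covariance at the truth
  CC <- tcrossprod(cov_factor(
    fit_loglinear_univariate(as.numeric(rmultinom(1, n, p)), 2, scores = x)))
  set.seed(9)
  B <- 2000
  boots <- matrix(NA_real_, B, length(x))
  for (b in seq_len(B)) {
    cb <- as.numeric(rmultinom(1, n, p))
    boots[b, ] <- tryCatch(
      fit_loglinear_univariate(cb, 2, scores = x)$fitted_probs,
      error = function(e) rep(NA_real_, length(x)))
  }
  emp <- var(boots[stats::complete.cases(boots), ])
  mid <- which(p > 0.05)  # compare where the variance is not minuscule
  expect_equal(diag(CC)[mid], diag(emp)[mid], tolerance = 0.15)
})

test_that("degenerate designs are rejected", {
  d <- toy5_counts()
  expect_error(fit_loglinear_univariate(d, 5), "degree")
  expect_error(fit_loglinear_univariate(score_dist(0:4, probs = rep(.2, 5)),
                                        2), "counts")
})
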