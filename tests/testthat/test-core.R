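# Gaussian-kernel continuization: shrinkage, CDF/pdf/derivative, inverse.

test_that("shrinkage factor follows its closed form and limits", {
  expect_equal(shrinkage_factor(4, 0), 1)
  expect_equal(shrinkage_factor(4, 2), 1 / sqrt(2))
  expect_equal(shrinkage_factor(163.3, 2.96),
               sqrt(163.3 / (163.3 + 2.96^2)), tolerance = 1e-12)
  expect_equal(round(shrinkage_factor(163.3, 2.96), 3), 0.974)
  expect_error(shrinkage_factor(0, 1), "degenerate")
  expect_error(shrinkage_factor(-1, 1), "degenerate")
  # a -> 0 as h -> infinity
  expect_lt(shrinkage_factor(4, 1e8), 1e-7)
})

test_that("score_dist validates its invariants", {
  expect_error(score_dist(c(0, 0, 1), probs = c(.3, .3, .4)), "increasing")
  expect_error(score_dist(0:2, probs = c(.5, .4, .2)), "sum to 1")
  expect_error(score_dist(0:1, probs = c(-.2, 1.2)), "nonnegative")
  expect_error(score_dist(c(0, 1.5), probs = c(.5, .5)), "integers")
  d <- score_dist(0:4, counts = c(5, 10, 20, 10, 5))
  expect_equal(d$probs, c(5, 10, 20, 10, 5) / 50)
  expect_equal(d$n, 50)
})

test_that("continuized CDF matches a term-by-term reference and symmetry", {
  cd <- continuize(toy3(), h = 1)
  expect_equal(kernel_cdf(cd, 1), 0.5, tolerance = 1e-12)
  # two-point symmetric base: cdf at the midpoint is 1/2 for any h
  d2 <- score_dist(0:1, probs = c(0.5, 0.5))
  for (h in c(0.1, 0.7, 3)) {
    expect_equal(kernel_cdf(continuize(d2, h), 0.5), 0.5, tolerance = 1e-12)
  }
  # off-center value against the independent three-term evaluation
  expect_equal(kernel_cdf(cd, 0.3), ref_cdf(toy3(), 1, 0.3),
               tolerance = 1e-12)
  grid <- seq(-3, 5, by = 0.05)
  expect_equal(kernel_cdf(cd, grid), ref_cdf(toy3(), 1, grid),
               tolerance = 1e-12)
  # nondecreasing, limits 0 and 1
  v <- kernel_cdf(cd, grid)
  expect_true(all(diff(v) >= 0))
  expect_lt(kernel_cdf(cd, -50), 1e-10)
  expect_gt(kernel_cdf(cd, 50), 1 - 1e-10)
})

test_that("pdf is normalized, matches reference, derivative is exact", {
  d <- score_dist(0:40, probs = rep(1 / 41, 41))
  cd <- continuize(d, h = 1)
  expect_equal(
    integrate(function(x) kernel_pdf(cd, x), -20, 60,
              rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
  cd3 <- continuize(toy3(), h = 1)
  expect_equal(kernel_pdf(cd3, c(0.3, 1.7)), ref_pdf(toy3(), 1, c(0.3, 1.7)),
               tolerance = 1e-12)
  # derivative vanishes at the center of a symmetric base
  expect_equal(kernel_pdf_deriv(cd3, 1), 0, tolerance = 1e-12)
  # closed-form derivative equals a central finite difference of the pdf
  eps <- 1e-5
  fd <- (kernel_pdf(cd3, 0.7 + eps) - kernel_pdf(cd3, 0.7 - eps)) / (2 * eps)
  expect_equal(kernel_pdf_deriv(cd3, 0.7), fd, tolerance = 1e-6)
  # and the pdf equals the derivative of the cdf
  fd2 <- (kernel_cdf(cd3, 0.7 + eps) - kernel_cdf(cd3, 0.7 - eps)) / (2 * eps)
  expect_equal(kernel_pdf(cd3, 0.7), fd2, tolerance = 1e-6)
})

test_that("moment preservation holds for any bandwidth", {
  d <- toy9()
  mu <- sd_mean(d); s2 <- sd_var(d)
  for (h in c(0.2, 1, 5, 50)) {
    cd <- continuize(d, h)
    m1 <- integrate(function(x) x * kernel_pdf(cd, x), -Inf, Inf,
                    rel.tol = 1e-10)$value
    m2 <- integrate(function(x) x^2 * kernel_pdf(cd, x), -Inf, Inf,
                    rel.tol = 1e-10)$value
    expect_equal(m1, mu, tolerance = 1e-6)
    expect_equal(m2 - m1^2, s2, tolerance = 1e-6)
  }
})

test_that("large- and small-bandwidth limits are the normal and discrete CDFs", {
  d <- toy9()
  mu <- sd_mean(d); sg <- sqrt(sd_var(d))
  cd <- continuize(d, 1e6)
  xs <- c(2, 4, 5.5, 7)
  expect_equal(kernel_cdf(cd, xs), pnorm((xs - mu) / sg), tolerance = 1e-4)
  # small h: cdf midway between adjacent scores approaches the discrete cdf
  cd0 <- continuize(d, 1e-3)
  expect_equal(kernel_cdf(cd0, d$scores[-length(d$scores)] + 0.5),
               cumsum(d$probs)[-length(d$probs)], tolerance = 1e-8)
})

test_that("inverse cdf round-trips, is monotone, and matches bisection", {
  cd <- continuize(toy9(), h = 0.8)
  xs <- seq(0.5, 7.5, by = 0.5)
  expect_equal(inverse_cdf(cd, kernel_cdf(cd, xs)), xs, tolerance = 1e-8)
  # symmetric base: median equals the mean
  cds <- continuize(toy3(), 0.9)
  expect_equal(inverse_cdf(cds, 0.5), 1, tolerance = 1e-8)
  ps <- c(0.05, 0.25, 0.5, 0.9)
  expect_true(all(diff(inverse_cdf(cd, ps)) > 0))
  # fine-grid bisection oracle at p = 0.25
  grid <- seq(-5, 15, by = 1e-4)
  oracle <- grid[which.min(abs(ref_cdf(toy9(), 0.8, grid) - 0.25))]
  expect_equal(inverse_cdf(cd, 0.25), oracle, tolerance = 1e-3)
  expect_error(inverse_cdf(cd, 0), "inside")
  expect_error(inverse_cdf(cd, 1.2), "inside")
})

test_that("degenerate distributions are rejected", {
  d1 <- score_dist(5L, probs = 1)
  expect_error(continuize(d1, 1), "variance|degenerate")
})
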