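# Small fixtures built in code, shared across test files.

toy3 <- function() score_dist(0:2, probs = c(0.25, 0.5, 0.25))

toy5_counts <- function() score_dist(0:4, counts = c(5, 10, 20, 10, 5))

# moderately smooth 9-point distribution with a known shape
toy9 <- function() {
  p <- dnorm(0:8, mean = 5, sd = 2)
  score_dist(0:8, probs = p / sum(p))
}

# jagged distribution that needs the smoothness penalty
jagged <- function() {
  p <- rep(c(0.3, 0.05), length.out = 9)
  score_dist(0:8, probs = p / sum(p))
}

# plain-R reference evaluation of the continuized CDF/pdf/derivative,
# independent of the compiled path
ref_cdf <- function(d, h, x) {
  mu <- sum(d$scores * d$probs)
  s2 <- sum(d$scores^2 * d$probs) - mu^2
  a <- sqrt(s2 / (s2 + h^2))
  sapply(x, function(xx)
    sum(d$probs * pnorm((xx - a * d$scores - (1 - a) * mu) / (a * h))))
}

ref_pdf <- function(d, h, x) {
  mu <- sum(d$scores * d$probs)
  s2 <- sum(d$scores^2 * d$probs) - mu^2
  a <- sqrt(s2 / (s2 + h^2))
  sapply(x, function(xx)
    sum(d$probs * dnorm((xx - a * d$scores - (1 - a) * mu) / (a * h))) /
      (a * h))
}

# continuized CDF for an arbitrary (possibly unnormalized) weight vector,
# with mu, sigma^2 and the shrinkage factor recomputed as functions of r —
# the finite-difference oracle for the SEE Jacobians
ref_cdf_raw <- function(scores, r, h, x) {
  mu <- sum(scores * r)
  s2 <- sum(scores^2 * r) - mu^2
  a <- sqrt(s2 / (s2 + h^2))
  sapply(x, function(xx)
    sum(r * pnorm((xx - a * scores - (1 - a) * mu) / (a * h))))
}

# classical percentile-rank equipercentile equating with linear
# interpolation (textbook oracle, no kernels)
classical_equipercentile <- function(x_scores, r, y_scores, s) {
  Fmid <- function(p) cumsum(p) - p / 2   # midpoint cdf at the scores
  Px <- Fmid(r)
  Gy <- Fmid(s)
  Gcum <- cumsum(s)
  sapply(Px, function(pr) {
    # y* with midpoint percentile rank pr, linear interpolation on the
    # piecewise-linear midpoint CDF of Y
    k <- findInterval(pr, Gy)
    if (k == 0) {
      y_scores[1] - 0.5 + (pr / Gcum[1])
    } else if (k >= length(y_scores)) {
      y_scores[length(y_scores)]
    } else {
      y_scores[k] + (pr - Gy[k]) / (Gy[k + 1] - Gy[k])
    }
  })
}
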