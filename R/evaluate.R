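# Accuracy and precision measures for equating estimators: PRE of moments,
# simulation MSE / per-score SE, the analytical (delta-method) SEE, a
# nonparametric bootstrap SEE, and difference-that-matters flags.

#' Percent relative error of moments
#'
#' Compares the first `p_max` raw moments of the equated scores, weighted
#' by the X score probabilities, with the corresponding moments of the Y
#' score distribution: `PRE(p) = 100 (mu_p(eqY(X)) - mu_p(Y)) / mu_p(Y)`.
#'
#' @param equated Equated value per X score point (or an
#'   `equating_result`).
#' @param r X score probabilities on the target population.
#' @param y_scores,s Y score grid and probabilities on the target
#'   population.
#' @param p_max Highest moment order (default 10).
#' @return Numeric vector of signed percentages, one per order.
#' @export
pre_moments <- function(equated, r, y_scores, s, p_max = 10) {
  if (inherits(equated, "equating_result")) equated <- equated$equated
  vapply(seq_len(p_max), function(p) {
    mu_p <- sum(y_scores^p * s)
    if (abs(mu_p) < .Machine$double.eps) {
      stop("moment of order ", p, " of Y is zero; PRE undefined")
    }
    100 * (sum(equated^p * r) - mu_p) / mu_p
  }, numeric(1))
}

#' Monte-Carlo mean squared error of the equated mean
#'
#' Squared bias of the replicate means plus their corrected (G - 1
#' divisor) sample variance.
#'
#' @param replicate_means Estimated equated-score means, one per
#'   replication.
#' @param mu_true True mean of the Y score distribution.
#' @return A single nonnegative number.
#' @export
mse_of_mean <- function(replicate_means, mu_true) {
  G <- length(replicate_means)
  if (G < 2) stop("at least two replications are required")
  (mean(replicate_means) - mu_true)^2 + var(replicate_means)
}

#' Per-score Monte-Carlo standard error
#'
#' Corrected sample standard deviation of the equated value at each X
#' score point across replications.
#'
#' @param replicate_curves G x J matrix, one equated curve per row.
#' @return Numeric vector of length J.
#' @export
se_per_score <- function(replicate_curves) {
  replicate_curves <- as.matrix(replicate_curves)
  if (nrow(replicate_curves) < 2) {
    stop("at least two replications are required")
  }
  apply(replicate_curves, 2, sd)
}

#' Difference-that-matters flags
#'
#' Flags the score points where two equated curves differ by more than
#' half a raw-score unit (strictly).
#'
#' @param curve_a,curve_b Equated curves on a common score grid.
#' @return Logical vector.
#' @export
dtm_compare <- function(curve_a, curve_b) {
  if (length(curve_a) != length(curve_b)) {
    stop("curves must share a common score grid")
  }
  abs(curve_a - curve_b) > 0.5
}

# Partial derivatives of the continuized CDF F(x; r) with respect to the
# probability vector, accounting for the dependence of mu, sigma^2 and the
# shrinkage factor on r:
#   dF/dr_m = Phi(z_m) + [S1 * da/dr_m - (1 - a) x_m S0] / (a h)
# with z_j = (x - a x_j - (1-a) mu)/(a h), S0 = sum_j r_j phi(z_j),
# S1 = sum_j r_j phi(z_j) (mu - x_j - z_j h), and
# da/dr_m = h^2 (x_m^2 - 2 mu x_m) / (2 a (sigma^2 + h^2)^2).
.dF_dr <- function(cd, x) {
  xs <- cd$base$scores; r <- cd$base$probs
  a <- cd$a; h <- cd$h; mu <- cd$mu; s2 <- cd$sigma2
  z <- outer(x, a * xs + (1 - a) * mu, "-") / (a * h)
  phi <- dnorm(z)
  S0 <- as.numeric(phi %*% r)
  S1 <- as.numeric((phi * sweep(mu - z * h, 2, xs, "-")) %*% r)
  da <- h^2 * (xs^2 - 2 * mu * xs) / (2 * a * (s2 + h^2)^2)
  pnorm(z) + (outer(S1, da) - outer((1 - a) * S0, xs)) / (a * h)
}

.see_vectors <- function(r, s, h_x, h_y) {
  cdx <- continuize(r, h_x)
  cdy <- continuize(s, h_y)
  p <- pmin(pmax(kernel_cdf(cdx, r$scores), 1e-15), 1 - 1e-15)
  phi_hat <- inverse_cdf(cdy, p)
  g <- kernel_pdf(cdy, phi_hat)
  tiny <- g < 1e-12
  if (any(tiny)) {
    warning("density of Y below 1e-12 at ", sum(tiny),
            " score(s); SEE unstable in the tails")
    g <- pmax(g, 1e-12)
  }
  vr <- .dF_dr(cdx, r$scores) / g
  vs <- -.dF_dr(cdy, phi_hat) / g
  list(vr = vr, vs = vs, equated = phi_hat)
}

# Jacobian blocks of the post-stratification design function with respect
# to the vectorized joint probabilities (cells column-major, test score
# fastest).
.pse_jacobian <- function(P, Q, w) {
  p <- P$probs; q <- Q$probs
  J <- nrow(p); K <- nrow(q); L <- ncol(p)
  pA <- colSums(p); qA <- colSums(q)
  dr_dp <- matrix(0, J, J * L); dr_dq <- matrix(0, J, K * L)
  ds_dq <- matrix(0, K, K * L); ds_dp <- matrix(0, K, J * L)
  for (l in seq_len(L)) {
    jp <- (l - 1) * J + seq_len(J)
    kq <- (l - 1) * K + seq_len(K)
    cl <- w + (1 - w) * qA[l] / pA[l]
    dr_dp[, jp] <- diag(cl, J) - outer(p[, l] * (1 - w) * qA[l] / pA[l]^2,
                                       rep(1, J))
    dr_dq[, kq] <- outer(p[, l] * (1 - w) / pA[l], rep(1, K))
    el <- (1 - w) + w * pA[l] / qA[l]
    ds_dq[, kq] <- diag(el, K) - outer(q[, l] * w * pA[l] / qA[l]^2,
                                       rep(1, K))
    ds_dp[, jp] <- outer(q[, l] * w / qA[l], rep(1, J))
  }
  rbind(cbind(dr_dp, dr_dq), cbind(ds_dp, ds_dq))
}

#' Analytical standard error of equating
#'
#' Delta-method SEE: per X score point, the Euclidean norm of the product
#' of the equating-function Jacobian (with respect to the score
#' probabilities), the design-function Jacobian (identity for EG,
#' post-stratification differentials for NEAT), and the covariance factor
#' C of the presmoothed probabilities. Bandwidths are treated as known
#' constants.
#'
#' @param x_input,y_input For EG: univariate [fit_loglinear_univariate()]
#'   fits, or [score_dist()]s with counts (then the raw multinomial
#'   covariance is used, i.e. no presmoothing). For NEAT: bivariate fits
#'   for populations P (X, A) and Q (Y, A).
#' @param spec A [ke_design()].
#' @param h_x,h_y Bandwidths.
#' @return An `equating_result` with the `see` component filled.
#' @export
see_analytical <- function(x_input, y_input, spec = ke_design("eg"),
                           h_x, h_y) {
  stopifnot(inherits(spec, "ke_design"))
  if (spec$design == "eg") {
    as_dist <- function(obj) {
      if (inherits(obj, "loglin_fit")) fitted_score_dist(obj) else obj
    }
    as_C <- function(obj) {
      if (inherits(obj, "loglin_fit")) cov_factor(obj)
      else {
        if (is.na(obj$n)) stop("sample size needed for the multinomial SEE")
        multinomial_cov_factor(obj$probs, obj$n)
      }
    }
    r <- as_dist(x_input); s <- as_dist(y_input)
    Cx <- as_C(x_input); Cy <- as_C(y_input)
    v <- .see_vectors(r, s, h_x, h_y)
    see <- sqrt(rowSums((v$vr %*% Cx)^2) + rowSums((v$vs %*% Cy)^2))
  } else {
    stopifnot(inherits(x_input, "loglin_fit"), x_input$type == "bivariate",
              inherits(y_input, "loglin_fit"), y_input$type == "bivariate")
    P <- fitted_biv_table(x_input); Q <- fitted_biv_table(y_input)
    ds <- design_function(spec, P, Q)
    r <- ds$r; s <- ds$s
    v <- .see_vectors(r, s, h_x, h_y)
    Jdf <- .pse_jacobian(P, Q, spec$weight)
    Cp <- cov_factor(x_input); Cq <- cov_factor(y_input)
    U <- cbind(v$vr, v$vs) %*% Jdf
    np <- nrow(Cp)
    see <- sqrt(rowSums((U[, seq_len(np), drop = FALSE] %*% Cp)^2) +
                  rowSums((U[, np + seq_len(nrow(Cq)), drop = FALSE] %*% Cq)^2))
  }
  out <- ke_equate(r, s, h_x, h_y)
  out$see <- see
  out
}

#' Bootstrap standard error of equating (EG design)
#'
#' Draws B nonparametric resamples of the test takers of each form
#' (multinomial on the observed proportions), re-runs the full pipeline —
#' optional presmoothing, bandwidth selection, equating — on each, and
#' returns the per-score corrected standard deviation of the equated
#' curves. Unlike the analytical SEE, bandwidth variability is captured
#' because bandwidths are re-selected per resample.
#'
#' @param x_dist,y_dist [score_dist()]s with raw counts.
#' @param B Number of bootstrap draws (>= 2).
#' @param seed Integer seed.
#' @param method Bandwidth selector re-run on each resample.
#' @param presmooth_degree Optional log-linear degree; `NULL` equates the
#'   raw proportions.
#' @param ... Passed to the bandwidth selector.
#' @return List with `see` (per-score SD), `curves` (B x J matrix) and
#'   `h` (B x 2 matrix of selected bandwidths).
#' @export
see_bootstrap <- function(x_dist, y_dist, B = 1000, seed = 1,
                          method = "penalty", presmooth_degree = NULL, ...) {
  stopifnot(inherits(x_dist, "score_dist"), inherits(y_dist, "score_dist"))
  if (is.null(x_dist$counts) || is.null(y_dist$counts)) {
    stop("bootstrap needs raw counts")
  }
  if (B < 2) stop("B must be >= 2")
  if (sd_var(x_dist) <= 0 || sd_var(y_dist) <= 0) {
    stop("degenerate score distribution: variance must be positive")
  }
  set.seed(seed)
  nx <- sum(x_dist$counts); ny <- sum(y_dist$counts)
  J <- length(x_dist$scores)
  curves <- matrix(NA_real_, B, J)
  hmat <- matrix(NA_real_, B, 2)
  for (b in seq_len(B)) {
    cx <- as.numeric(rmultinom(1, nx, x_dist$probs))
    cy <- as.numeric(rmultinom(1, ny, y_dist$probs))
    dx <- score_dist(x_dist$scores, counts = cx)
    dy <- score_dist(y_dist$scores, counts = cy)
    if (!is.null(presmooth_degree)) {
      dx <- fitted_score_dist(fit_loglinear_univariate(dx, presmooth_degree))
      dy <- fitted_score_dist(fit_loglinear_univariate(dy, presmooth_degree))
    }
    hx <- select_bandwidth(dx, method, ...)$h
    hy <- select_bandwidth(dy, method, ...)$h
    curves[b, ] <- ke_equate(dx, dy, hx, hy)$equated
    hmat[b, ] <- c(hx, hy)
  }
  list(see = se_per_score(curves), curves = curves, h = hmat)
}
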