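# Data-driven bandwidth selection for the Gaussian-kernel continuization.
#
# Six selectors are provided. Four minimize an explicit criterion in h
# (penalty, DS, LCV, PLCV), one is a closed form (SRT), and one is a
# stochastic split-sample grid search (LiCV).

.bw_methods <- c("penalty", "srt", "ds", "licv", "lcv", "plcv")

.bw_result <- function(method, h, criterion_value = NA_real_,
                       diagnostics = list()) {
  structure(
    list(method = method, h = h, criterion_value = criterion_value,
         diagnostics = diagnostics),
    class = "bandwidth_selection"
  )
}

#' @export
print.bandwidth_selection <- function(x, ...) {
  cat("<bandwidth_selection> method = ", x$method,
      ", h = ", format(x$h, digits = 5), "\n", sep = "")
  invisible(x)
}

# Minimize f(h) over [lower, upper] on the log scale: golden-section /
# parabolic search (stats::optimize) on `restarts` log-spaced subintervals,
# then one local refinement around the best point.
.optimize_bandwidth <- function(f, lower = 0.01, upper = 30, restarts = 5) {
  edges <- exp(seq(log(lower), log(upper), length.out = restarts + 1))
  g <- function(lh) f(exp(lh))
  best <- NULL
  for (i in seq_len(restarts)) {
    o <- optimize(g, lower = log(edges[i]), upper = log(edges[i + 1]),
                  tol = 1e-7)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  span <- (log(upper) - log(lower)) / restarts
  o <- optimize(g, lower = max(log(lower), best$minimum - span),
                upper = min(log(upper), best$minimum + span), tol = 1e-8)
  if (o$objective < best$objective) best <- o
  list(h = exp(best$minimum), value = best$objective)
}

#' Sign-change penalty count
#'
#' Counts score points x_j near which the derivative of the continuized
#' density changes sign, the smoothness penalty shared by the penalty and
#' PLCV selectors. The default `direction = "valley"` flags a slope change
#' from negative at x_j - w to positive at x_j + w, i.e. a U-shape: an
#' undersmoothed estimate develops a valley between adjacent score masses,
#' while a genuine mode is never penalized. `direction = "both"` also
#' flags modes (positive-to-negative flips); note that with that variant
#' any unimodal density is penalized whenever its mode falls within w of a
#' score point, which overwhelms the squared-distance term of the penalty
#' criterion and drives the selected bandwidth toward the normal limit.
#'
#' @param dist A [score_dist()].
#' @param h Bandwidth (> 0).
#' @param w Neighborhood half-width, raw-score units (default 0.25).
#' @param direction `"valley"` (default) or `"both"`.
#' @return Integer count of flagged score points.
#' @export
penalty_term <- function(dist, h, w = 0.25,
                         direction = c("valley", "both")) {
  stopifnot(inherits(dist, "score_dist"))
  direction <- match.arg(direction)
  if (w <= 0) stop("w must be positive")
  cd <- continuize(dist, h)
  dl <- kernel_pdf_deriv(cd, dist$scores - w)
  dr <- kernel_pdf_deriv(cd, dist$scores + w)
  .pen_count(dl, dr, direction)
}

.pen_count <- function(dl, dr, direction) {
  if (direction == "valley") sum(dl < 0 & dr > 0)
  else sum((dl > 0 & dr < 0) | (dl < 0 & dr > 0))
}

.pen_criterion <- function(dist, kappa, w, direction = "valley") {
  x <- dist$scores; r <- dist$probs
  mu <- sd_mean(dist); s2 <- sd_var(dist)
  function(h) {
    a <- shrinkage_factor(s2, h)
    f <- .gm_eval_cpp(x, x, r, mu, a, h, 1L)
    pen <- 0
    if (kappa != 0) {
      dl <- .gm_eval_cpp(x - w, x, r, mu, a, h, 2L)
      dr <- .gm_eval_cpp(x + w, x, r, mu, a, h, 2L)
      pen <- .pen_count(dl, dr, direction)
    }
    sum((r - f)^2) + kappa * pen
  }
}

#' Penalty-method bandwidth
#'
#' Minimizes the sum of squared distances between the score probabilities
#' and the continuized density at the score points, plus `kappa` times the
#' sign-change penalty of [penalty_term()].
#'
#' @param dist A [score_dist()] (typically presmoothed).
#' @param kappa Penalty weight (default 1; 0 drops the penalty).
#' @param w Penalty neighborhood half-width (default 0.25).
#' @param direction Sign-change variant, see [penalty_term()].
#' @param lower,upper Search range for h.
#' @return A `bandwidth_selection`.
#' @export
select_penalty <- function(dist, kappa = 1, w = 0.25,
                           direction = c("valley", "both"),
                           lower = 0.01, upper = 30) {
  direction <- match.arg(direction)
  crit <- .pen_criterion(dist, kappa, w, direction)
  o <- .optimize_bandwidth(crit, lower, upper)
  .bw_result("penalty", o$h, o$value,
             list(kappa = kappa, w = w,
                  penalty_count = penalty_term(dist, o$h, w, direction)))
}

#' Silverman's rule of thumb, adjusted for the shrinkage factor
#'
#' Closed form h = 9 sigma / sqrt(100 n^(2/5) - 81), obtained by equating
#' the effective kernel scale a*h of the continuization to Silverman's
#' 0.9 sigma n^(-1/5) for a normal reference density.
#'
#' @param dist A [score_dist()] with known sample size `n`.
#' @param n Sample size override.
#' @return A `bandwidth_selection`.
#' @export
select_srt <- function(dist, n = dist$n) {
  stopifnot(inherits(dist, "score_dist"))
  if (is.na(n) || n < 1) stop("sample size n >= 1 is required for SRT")
  s2 <- sd_var(dist)
  if (s2 <= 0) stop("degenerate score distribution: variance must be positive")
  denom <- 100 * n^(2 / 5) - 81
  if (denom <= 0) stop("sample size too small for the SRT formula")
  h <- 9 * sqrt(s2) / sqrt(denom)
  .bw_result("srt", h, diagnostics = list(sigma = sqrt(s2), n = n))
}

# Double-smoothing helpers: the evaluation grid interleaves the score
# points with their midpoints, length 2J - 1.
.ds_grid <- function(scores) {
  J <- length(scores)
  grid <- numeric(2 * J - 1)
  grid[seq(1, 2 * J - 1, by = 2)] <- scores
  grid[seq(2, 2 * J - 2, by = 2)] <- (scores[-J] + scores[-1]) / 2
  grid
}

.ds_criterion <- function(dist, q) {
  x <- dist$scores; r <- dist$probs
  mu <- sd_mean(dist); s2 <- sd_var(dist)
  grid <- .ds_grid(x)
  J <- length(x)
  odd <- seq(1, 2 * J - 1, by = 2)
  aq <- shrinkage_factor(s2, q)
  pilot_grid <- .gm_eval_cpp(grid, x, r, mu, aq, q, 1L)
  # pilot density at the score points, renormalized to a probability
  # vector, replaces r as the mixture weights of the DS estimate
  wts <- pilot_grid[odd] / sum(pilot_grid[odd])
  target <- pilot_grid
  target[odd] <- r
  function(h) {
    a <- shrinkage_factor(s2, h)
    fstar <- .gm_eval_cpp(grid, x, wts, mu, a, h, 1L)
    sum((target - fstar)^2)
  }
}

#' Double-smoothing bandwidth
#'
#' A large pilot bandwidth `q` first produces an oversmoothed density.
#' Its values at the score points then serve as mixture weights for a
#' second kernel estimate, which is matched against the observed
#' probabilities at the score points and against the pilot density at the
#' midpoints between them.
#'
#' @param dist A [score_dist()] (typically presmoothed).
#' @param q Pilot bandwidth; default 3 times the SRT bandwidth ("large,
#'   subjectively chosen").
#' @param lower,upper Search range for h.
#' @return A `bandwidth_selection`.
#' @export
select_ds <- function(dist, q = NULL, lower = 0.01, upper = 30) {
  stopifnot(inherits(dist, "score_dist"))
  if (is.null(q)) q <- 3 * select_srt(dist)$h
  if (q <= 0) stop("pilot bandwidth must be positive")
  crit <- .ds_criterion(dist, q)
  o <- .optimize_bandwidth(crit, lower, upper)
  .bw_result("ds", o$h, o$value, list(pilot = q))
}

.lcv_criterion <- function(dist) {
  x <- dist$scores; r <- dist$probs
  mu <- sd_mean(dist); s2 <- sd_var(dist)
  J <- length(x)
  function(h) {
    a <- shrinkage_factor(s2, h)
    floo <- .gm_loo_cpp(x, r, mu, a, h)
    sum((r - floo)^2) / J
  }
}

#' Leave-one-out cross-validation bandwidth
#'
#' Minimizes the mean squared distance between each score probability and
#' the kernel density at that score rebuilt from the remaining score
#' points. The left-out mixture weights are not renormalized; the
#' shrinkage factor and mean stay those of the full distribution.
#'
#' @param dist A [score_dist()] with at least two score points.
#' @param lower,upper Search range for h.
#' @return A `bandwidth_selection`.
#' @export
select_lcv <- function(dist, lower = 0.01, upper = 30) {
  stopifnot(inherits(dist, "score_dist"))
  if (length(dist$scores) < 2) stop("at least two score points are required")
  crit <- .lcv_criterion(dist)
  o <- .optimize_bandwidth(crit, lower, upper)
  .bw_result("lcv", o$h, o$value)
}

#' Penalized leave-one-out cross-validation bandwidth
#'
#' The [select_lcv()] criterion plus `kappa` times the sign-change penalty
#' of [penalty_term()]; with `kappa = 0` it reduces exactly to LCV.
#'
#' @inheritParams select_penalty
#' @return A `bandwidth_selection`.
#' @export
select_plcv <- function(dist, kappa = 1, w = 0.25,
                        direction = c("valley", "both"),
                        lower = 0.01, upper = 30) {
  stopifnot(inherits(dist, "score_dist"))
  direction <- match.arg(direction)
  if (length(dist$scores) < 2) stop("at least two score points are required")
  lcv <- .lcv_criterion(dist)
  x <- dist$scores; r <- dist$probs
  mu <- sd_mean(dist); s2 <- sd_var(dist)
  crit <- function(h) {
    pen <- 0
    if (kappa != 0) {
      a <- shrinkage_factor(s2, h)
      dl <- .gm_eval_cpp(x - w, x, r, mu, a, h, 2L)
      dr <- .gm_eval_cpp(x + w, x, r, mu, a, h, 2L)
      pen <- .pen_count(dl, dr, direction)
    }
    lcv(h) + kappa * pen
  }
  o <- .optimize_bandwidth(crit, lower, upper)
  .bw_result("plcv", o$h, o$value,
             list(kappa = kappa, w = w,
                  penalty_count = penalty_term(dist, o$h, w, direction)))
}

#' Likelihood cross-validation bandwidth
#'
#' Repeatedly half-splits the test takers at random. Each repeat builds a
#' kernel density from the first subsample's score probabilities and
#' scores it against the second subsample's frequencies through a Poisson
#' likelihood, maximized over a fixed bandwidth grid; the selected
#' bandwidth is the median of the per-repeat maximizers.
#'
#' By default the first subsample is presmoothed with an
#' information-criterion-selected polynomial log-linear model (degrees
#' `degrees`), mirroring the standard kernel-equating pipeline in which
#' densities are built from presmoothed probabilities; `presmooth =
#' "none"` uses the raw subsample proportions instead. The shrinkage
#' factor and mean are taken from the same subsample probabilities.
#'
#' @param dist A [score_dist()] carrying raw counts (individual-level
#'   resampling is required).
#' @param grid Bandwidth grid (default `seq(0.01, 5, by = 0.01)`).
#' @param n_repeats Number of random splits (default 1000).
#' @param seed Optional integer seed for the splits.
#' @param presmooth `"bic"`, `"aic"` (criterion for the subsample
#'   log-linear model) or `"none"`.
#' @param degrees Candidate degrees for the subsample presmoothing.
#' @return A `bandwidth_selection`; `diagnostics$h_sample` holds the
#'   per-repeat maximizers.
#' @export
select_licv <- function(dist, grid = seq(0.01, 5, by = 0.01),
                        n_repeats = 1000, seed = NULL,
                        presmooth = c("bic", "aic", "none"),
                        degrees = 2:6) {
  stopifnot(inherits(dist, "score_dist"))
  presmooth <- match.arg(presmooth)
  if (is.null(dist$counts)) stop("LiCV needs raw counts")
  if (length(grid) < 1) stop("bandwidth grid must be nonempty")
  n <- sum(dist$counts)
  if (n < 2) stop("at least two test takers are required")
  if (!is.null(seed)) set.seed(seed)
  x <- dist$scores
  indiv <- rep.int(x, dist$counts)
  n1 <- ceiling(n / 2)
  hs <- numeric(n_repeats)
  for (b in seq_len(n_repeats)) {
    idx <- sample.int(n, n1)
    c1 <- tabulate(match(indiv[idx], x), nbins = length(x))
    c2 <- tabulate(match(indiv[-idx], x), nbins = length(x))
    r1 <- c1 / n1
    if (presmooth != "none") {
      sm <- tryCatch(
        select_model(score_dist(x, counts = c1), degrees, presmooth),
        error = function(e) NULL)
      if (!is.null(sm)) r1 <- sm$fitted_probs
    }
    mu1 <- sum(x * r1)
    v1 <- sum(x^2 * r1) - mu1^2
    if (v1 <= 0) { hs[b] <- NA_real_; next }
    ll <- .licv_loglik_grid_cpp(x, r1, mu1, v1, c2, n1, grid)
    hs[b] <- grid[which.max(ll)]
  }
  hs <- hs[!is.na(hs)]
  if (!length(hs)) stop("all LiCV splits were degenerate")
  .bw_result("licv", median(hs),
             diagnostics = list(h_sample = hs, grid_range = range(grid),
                                n_repeats = n_repeats,
                                presmooth = presmooth))
}

#' Select a bandwidth by any of the six methods
#'
#' Dispatcher over [select_penalty()], [select_srt()], [select_ds()],
#' [select_licv()], [select_lcv()] and [select_plcv()].
#'
#' @param dist A [score_dist()].
#' @param method One of `"penalty"`, `"srt"`, `"ds"`, `"licv"`, `"lcv"`,
#'   `"plcv"`.
#' @param ... Passed to the specific selector.
#' @return A `bandwidth_selection`.
#' @export
select_bandwidth <- function(dist, method = .bw_methods, ...) {
  method <- match.arg(method)
  switch(method,
         penalty = select_penalty(dist, ...),
         srt = select_srt(dist, ...),
         ds = select_ds(dist, ...),
         licv = select_licv(dist, ...),
         lcv = select_lcv(dist, ...),
         plcv = select_plcv(dist, ...))
}
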