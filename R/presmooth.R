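# Log-linear (polynomial Poisson) presmoothing of score frequencies.
#
# The design regresses cell counts on polynomial score terms; by the score
# equations of the Poisson log-linear family the fitted distribution
# reproduces the observed moments of every preserved order exactly.
# Polynomial columns are centered and scaled before fitting for
# conditioning; fitted probabilities are invariant to that
# reparametrization (same column space).

.poly_cols <- function(x, degree, label) {
  xs <- (x - mean(x)) / stats::sd(x)
  cols <- lapply(seq_len(degree), function(p) xs^p)
  names(cols) <- paste0(label, seq_len(degree))
  cols
}

.fit_poisson <- function(B, counts) {
  # B excludes the intercept; glm.fit adds it
  X <- cbind(`(Intercept)` = 1, B)
  fit <- suppressWarnings(
    glm.fit(X, counts, family = poisson(), control = list(maxit = 100))
  )
  if (!fit$converged) stop("log-linear fit did not converge (design with ",
                           ncol(B), " terms)")
  if (fit$rank < ncol(X)) stop("rank-deficient log-linear design")
  fit
}

.loglin_result <- function(fit, B, counts, design, type, extra = list()) {
  n <- sum(counts)
  fitted_probs <- fit$fitted.values / n
  k <- ncol(B) + 1L
  # Poisson log-likelihood including constants, so AIC is comparable
  # across designs on the same data
  ll <- sum(stats::dpois(counts, fit$fitted.values, log = TRUE))
  out <- c(list(
    design = design, type = type, fitted_probs = fitted_probs,
    counts = counts, n = n, B = B, k = k, loglik = ll,
    aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(n)
  ), extra)
  class(out) <- "loglin_fit"
  out
}

#' Univariate log-linear presmoothing
#'
#' Fits a Poisson regression of score frequencies on polynomial score terms
#' of orders 1..degree. The fitted probabilities are strictly positive on
#' the full grid and match the observed raw moments up to `degree`.
#'
#' @param dist A [score_dist()] carrying counts, or a numeric vector of
#'   counts on `scores`.
#' @param degree Highest preserved moment (>= 1).
#' @param scores Score grid when `dist` is a bare count vector.
#' @return An object of class `loglin_fit`: `fitted_probs`, `aic`, `bic`,
#'   `design`, and the data needed by [cov_factor()].
#' @examples
#' d <- score_dist(0:4, counts = c(5, 10, 20, 10, 5))
#' f <- fit_loglinear_univariate(d, degree = 2)
#' sum(f$fitted_probs * 0:4)  # equals the observed mean 2
#' @export
fit_loglinear_univariate <- function(dist, degree, scores = NULL) {
  if (inherits(dist, "score_dist")) {
    if (is.null(dist$counts)) stop("presmoothing needs raw counts")
    counts <- dist$counts
    scores <- dist$scores
  } else {
    counts <- as.numeric(dist)
    if (is.null(scores)) stop("scores must be given with a bare count vector")
  }
  if (sum(counts) <= 0) stop("total count must be positive")
  if (degree < 1) stop("degree must be >= 1")
  if (degree >= sum(counts > 0)) {
    stop("degree must be smaller than the number of occupied score points")
  }
  B <- do.call(cbind, .poly_cols(scores, degree, "x"))
  fit <- .fit_poisson(B, counts)
  .loglin_result(fit, B, counts, design = list(degree = degree),
                 type = "univariate", extra = list(scores = scores))
}

#' Bivariate log-linear presmoothing
#'
#' Fits a Poisson log-linear model to a joint (test score, anchor score)
#' frequency table with polynomial margins of degrees `deg_x`, `deg_a` and
#' the cross-moment terms listed in `cross` (pairs of powers `(i, j)`
#' entering as `x^i * a^j`).
#'
#' @param tab A [biv_table()] carrying counts.
#' @param deg_x,deg_a Highest preserved marginal moments.
#' @param cross List of integer pairs of cross-moment orders, e.g.
#'   `list(c(1, 1), c(2, 2))`. Empty list for independence-style fits.
#' @return A `loglin_fit` whose `fitted_probs` is the J x L matrix of
#'   fitted joint probabilities.
#' @export
fit_loglinear_bivariate <- function(tab, deg_x, deg_a, cross = list(c(1, 1))) {
  stopifnot(inherits(tab, "biv_table"))
  if (is.null(tab$counts)) stop("presmoothing needs raw counts")
  J <- length(tab$x_scores); L <- length(tab$a_scores)
  xg <- rep(tab$x_scores, times = L)
  ag <- rep(tab$a_scores, each = J)
  counts <- as.numeric(tab$counts)  # column-major: x fastest
  xc <- .poly_cols(xg, deg_x, "x")
  ac <- .poly_cols(ag, deg_a, "a")
  cc <- list()
  if (length(cross)) {
    xs <- (xg - mean(xg)) / stats::sd(xg)
    as_ <- (ag - mean(ag)) / stats::sd(ag)
    for (pr in cross) {
      cc[[paste0("x", pr[1], "a", pr[2])]] <- xs^pr[1] * as_^pr[2]
    }
  }
  B <- do.call(cbind, c(xc, ac, cc))
  fit <- .fit_poisson(B, counts)
  res <- .loglin_result(
    fit, B, counts,
    design = list(deg_x = deg_x, deg_a = deg_a, cross = cross),
    type = "bivariate",
    extra = list(x_scores = tab$x_scores, a_scores = tab$a_scores)
  )
  res$fitted_matrix <- matrix(res$fitted_probs, J, L)
  res
}

#' @export
print.loglin_fit <- function(x, ...) {
  cat("<loglin_fit> ", x$type, ", ", x$k, " parameters, AIC ",
      format(x$aic, digits = 6), ", BIC ", format(x$bic, digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' Presmoothed score distribution from a fit
#'
#' @param fit A univariate `loglin_fit`.
#' @return A [score_dist()] with the fitted probabilities and the original
#'   counts.
#' @export
fitted_score_dist <- function(fit) {
  stopifnot(inherits(fit, "loglin_fit"), fit$type == "univariate")
  score_dist(fit$scores, probs = fit$fitted_probs, counts = fit$counts,
             n = fit$n)
}

#' Presmoothed bivariate table from a fit
#'
#' @param fit A bivariate `loglin_fit`.
#' @return A [biv_table()] with the fitted joint probabilities and the
#'   original counts.
#' @export
fitted_biv_table <- function(fit) {
  stopifnot(inherits(fit, "loglin_fit"), fit$type == "bivariate")
  biv_table(fit$x_scores, fit$a_scores, probs = fit$fitted_matrix,
            counts = matrix(fit$counts, length(fit$x_scores)), n = fit$n)
}

#' Information-criterion model selection for presmoothing
#'
#' Fits every candidate design and returns the one minimizing AIC
#' (customary under the equivalent-groups design) or BIC (customary for
#' bivariate NEAT smoothing). Ties break toward fewer parameters.
#'
#' @param data A [score_dist()] with counts, or a [biv_table()] with counts.
#' @param candidates For univariate data an integer vector of degrees; for
#'   bivariate data a list of lists with elements `deg_x`, `deg_a`, `cross`.
#'   Defaults: degrees 2:6 (univariate); marginal degrees 2:4 crossed with
#'   the cross-moment sets `{}`, `{(1,1)}`, `{(1,1),(1,2),(2,1)}`,
#'   `{(1,1),(2,2)}` (bivariate).
#' @param criterion `"aic"` or `"bic"`.
#' @return The winning `loglin_fit` (component `criterion_table` lists all
#'   converged candidates).
#' @export
select_model <- function(data, candidates = NULL,
                         criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  if (inherits(data, "score_dist")) {
    if (is.null(candidates)) candidates <- 2:6
    fits <- lapply(candidates, function(d) {
      tryCatch(fit_loglinear_univariate(data, d), error = function(e) NULL)
    })
    labels <- paste0("degree=", candidates)
  } else if (inherits(data, "biv_table")) {
    if (is.null(candidates)) {
      cross_sets <- list(list(), list(c(1, 1)),
                         list(c(1, 1), c(1, 2), c(2, 1)),
                         list(c(1, 1), c(2, 2)))
      candidates <- list()
      for (dx in 2:4) for (cs in cross_sets) {
        candidates[[length(candidates) + 1L]] <-
          list(deg_x = dx, deg_a = dx, cross = cs)
      }
    }
    fits <- lapply(candidates, function(d) {
      tryCatch(
        fit_loglinear_bivariate(data, d$deg_x, d$deg_a, d$cross),
        error = function(e) NULL
      )
    })
    labels <- vapply(candidates, function(d) {
      paste0("deg_x=", d$deg_x, ",deg_a=", d$deg_a,
             ",cross=", length(d$cross))
    }, character(1))
  } else stop("data must be a score_dist or biv_table with counts")
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no candidate presmoothing model converged")
  fits <- fits[ok]; labels <- labels[ok]
  crit <- vapply(fits, function(f) f[[criterion]], numeric(1))
  k <- vapply(fits, function(f) f$k, numeric(1))
  best <- order(crit, k)[1L]
  out <- fits[[best]]
  out$criterion_table <- data.frame(
    candidate = labels, k = k, value = crit, row.names = NULL
  )
  out$criterion_used <- criterion
  out
}

#' Covariance factor of the presmoothed probabilities
#'
#' Returns a matrix C with `C %*% t(C)` equal to the asymptotic covariance
#' of the fitted probability vector of a log-linear fit: with
#' `M = diag(pi) - pi pi'` and design B (intercept excluded),
#' `Cov = M B (B' M B)^{-1} B' M / n`, the delta-method covariance of the
#' multinomial log-linear MLE. With a saturated design this reduces to the
#' multinomial covariance `M / n`.
#'
#' @param fit A `loglin_fit`.
#' @return A (cells x parameters) matrix C.
#' @export
cov_factor <- function(fit) {
  stopifnot(inherits(fit, "loglin_fit"))
  p <- fit$fitted_probs
  B <- fit$B
  MB <- p * B - p * as.numeric(crossprod(B, p))[col(B)]
  # MB = (diag(p) - p p') B, computed column-wise
  K <- crossprod(B, MB)
  K <- (K + t(K)) / 2
  R <- tryCatch(chol(K), error = function(e)
    stop("singular information matrix in cov_factor"))
  (MB %*% backsolve(R, diag(ncol(B)))) / sqrt(fit$n)
}

#' Multinomial covariance factor (no presmoothing)
#'
#' Factor C with `C %*% t(C) = (diag(r) - r r') / n`, the sampling
#' covariance of raw sample proportions; used for equating without
#' presmoothing.
#'
#' @param probs Probability vector.
#' @param n Sample size.
#' @return A square matrix C.
#' @export
multinomial_cov_factor <- function(probs, n) {
  u <- sqrt(probs)
  (diag(u) - outer(probs, u)) / sqrt(n)
}
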