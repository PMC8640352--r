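# Design functions and the kernel equipercentile transformation.

#' Design specification
#'
#' @param design `"eg"` (equivalent groups) or `"neat_pse"`
#'   (non-equivalent groups with anchor, post-stratification).
#' @param weight Target-population weight w for population P,
#'   T = w P + (1 - w) Q. Ignored for EG.
#' @return An object of class `ke_design`.
#' @export
ke_design <- function(design = c("eg", "neat_pse"), weight = 0.5) {
  design <- match.arg(design)
  if (weight < 0 || weight > 1) stop("weight must lie in [0, 1]")
  structure(list(design = design, weight = weight), class = "ke_design")
}

#' Map presmoothed distributions to target-population score probabilities
#'
#' Under the EG design the presmoothed marginals are the target
#' probabilities unchanged. Under NEAT post-stratification, each
#' population's conditional score distribution given the anchor is
#' reweighted by the target-population anchor distribution
#' `w * Pr(A|P) + (1 - w) * Pr(A|Q)`.
#'
#' @param spec A [ke_design()].
#' @param x_data For EG a [score_dist()] for form X; for NEAT a
#'   [biv_table()] of (X, A) on population P (presmoothed: strictly
#'   positive anchor margins are required).
#' @param y_data For EG a [score_dist()] for form Y; for NEAT a
#'   [biv_table()] of (Y, A) on population Q.
#' @return A list with [score_dist()]s `r` (X scores on T) and `s`
#'   (Y scores on T).
#' @export
design_function <- function(spec, x_data, y_data) {
  stopifnot(inherits(spec, "ke_design"))
  if (spec$design == "eg") {
    stopifnot(inherits(x_data, "score_dist"), inherits(y_data, "score_dist"))
    return(list(r = x_data, s = y_data))
  }
  stopifnot(inherits(x_data, "biv_table"), inherits(y_data, "biv_table"))
  if (length(x_data$a_scores) != length(y_data$a_scores) ||
      any(x_data$a_scores != y_data$a_scores)) {
    stop("anchor score grids of the two populations must match")
  }
  w <- spec$weight
  pA <- colSums(x_data$probs)
  qA <- colSums(y_data$probs)
  if (any(pA <= 0) || any(qA <= 0)) {
    stop("zero anchor-marginal cell; presmooth the joint tables first")
  }
  tA <- w * pA + (1 - w) * qA
  r <- as.numeric(x_data$probs %*% (tA / pA))
  s <- as.numeric(y_data$probs %*% (tA / qA))
  list(
    r = score_dist(x_data$x_scores, probs = r, n = x_data$n),
    s = score_dist(y_data$x_scores, probs = s, n = y_data$n)
  )
}

#' Kernel equipercentile equating
#'
#' Equates form X to form Y by the composition
#' `G^{-1}(F(x))` of the two continuized CDFs: each X score point is
#' mapped to the Y-scale value with the same cumulative probability.
#'
#' @param r [score_dist()] of X scores on the target population.
#' @param s [score_dist()] of Y scores on the target population.
#' @param h_x,h_y Bandwidths for the two continuizations.
#' @param method Optional label naming the bandwidth method used.
#' @return An object of class `equating_result`: `x_scores`, `equated`,
#'   the bandwidths, and slots for per-score standard errors.
#' @examples
#' r <- score_dist(0:4, probs = c(.1, .2, .4, .2, .1))
#' eq <- ke_equate(r, r, h_x = 0.5, h_y = 0.5)
#' all.equal(eq$equated, as.numeric(0:4))  # identity equating
#' @export
ke_equate <- function(r, s, h_x, h_y, method = NA_character_) {
  stopifnot(inherits(r, "score_dist"), inherits(s, "score_dist"))
  cdx <- continuize(r, h_x)
  cdy <- continuize(s, h_y)
  p <- kernel_cdf(cdx, r$scores)
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  eq <- inverse_cdf(cdy, p)
  structure(
    list(x_scores = r$scores, equated = eq, h_x = h_x, h_y = h_y,
         see = NULL, method = method, r = r, s = s),
    class = "equating_result"
  )
}

#' @export
print.equating_result <- function(x, ...) {
  cat("<equating_result> ", length(x$x_scores), " score points, h_x = ",
      format(x$h_x, digits = 4), ", h_y = ", format(x$h_y, digits = 4),
      if (!is.na(x$method)) paste0(" (", x$method, ")"), "\n", sep = "")
  df <- data.frame(x = x$x_scores, equated = x$equated)
  if (!is.null(x$see)) df$see <- x$see
  print(utils::head(df, 10), row.names = FALSE)
  if (length(x$x_scores) > 10) cat("  ...\n")
  invisible(x)
}
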