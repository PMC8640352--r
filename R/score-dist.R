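#' Discrete score distribution
#'
#' Container for the score-probability vector of one test form: ordered
#' integer score values with a probability per score and, optionally, the
#' raw frequencies they were estimated from.
#'
#' @param scores Integer score values, strictly increasing.
#' @param probs Probability per score (nonnegative, summing to 1). If
#'   omitted, derived from `counts`.
#' @param counts Optional nonnegative integer frequencies on the same grid.
#' @param n Total sample size; defaults to `sum(counts)` when counts are given.
#'
#' @return An object of class `score_dist` with elements `scores`, `probs`,
#'   `counts` (possibly `NULL`) and `n` (possibly `NA`).
#' @examples
#' d <- score_dist(0:4, counts = c(5, 10, 20, 10, 5))
#' sd_mean(d)
#' @export
score_dist <- function(scores, probs = NULL, counts = NULL, n = NULL) {
  scores <- as.numeric(scores)
  if (length(scores) < 1L) stop("at least one score value is required")
  if (any(scores != round(scores))) stop("scores must be integers")
  if (is.unsorted(scores, strictly = TRUE)) {
    stop("scores must be strictly increasing")
  }
  if (is.null(probs)) {
    if (is.null(counts)) stop("either probs or counts must be supplied")
    if (sum(counts) <= 0) stop("total count must be positive")
    probs <- counts / sum(counts)
  }
  probs <- as.numeric(probs)
  if (length(probs) != length(scores)) {
    stop("scores and probs must have the same length")
  }
  if (any(probs < 0)) {
    if (min(probs) > -1e-8) probs <- pmax(probs, 0) else {
      stop("probabilities must be nonnegative")
    }
  }
  dev <- abs(sum(probs) - 1)
  if (dev >= 1e-8) stop("probabilities must sum to 1 (deviation ", dev, ")")
  if (dev > 1e-10) probs <- probs / sum(probs)
  if (!is.null(counts)) {
    counts <- as.numeric(counts)
    if (length(counts) != length(scores)) {
      stop("scores and counts must have the same length")
    }
    if (any(counts < 0) || any(counts != round(counts))) {
      stop("counts must be nonnegative integers")
    }
    if (is.null(n)) n <- sum(counts)
  }
  structure(
    list(scores = scores, probs = probs, counts = counts,
         n = if (is.null(n)) NA_real_ else as.numeric(n)),
    class = "score_dist"
  )
}

#' @export
print.score_dist <- function(x, ...) {
  cat("<score_dist> ", length(x$scores), " score points on [",
      min(x$scores), ", ", max(x$scores), "]",
      if (!is.na(x$n)) paste0(", n = ", x$n), "\n", sep = "")
  cat("  mean ", format(sd_mean(x), digits = 5),
      ", sd ", format(sqrt(sd_var(x)), digits = 5), "\n", sep = "")
  invisible(x)
}

#' Mean and variance of a discrete score distribution
#'
#' @param d A [score_dist()].
#' @return A single number.
#' @export
sd_mean <- function(d) sum(d$scores * d$probs)

#' @rdname sd_mean
#' @export
sd_var <- function(d) sum(d$scores^2 * d$probs) - sd_mean(d)^2

#' Bivariate score table
#'
#' Joint distribution of a test score and an anchor score for one
#' population under the NEAT design. Rows index test scores, columns
#' anchor scores.
#'
#' @param x_scores Integer test-score values (strictly increasing).
#' @param a_scores Integer anchor-score values (strictly increasing).
#' @param probs J x L matrix of joint probabilities; derived from `counts`
#'   if omitted.
#' @param counts Optional J x L matrix of frequencies.
#' @param n Total sample size; defaults to `sum(counts)`.
#'
#' @return An object of class `biv_table`.
#' @export
biv_table <- function(x_scores, a_scores, probs = NULL, counts = NULL, n = NULL) {
  x_scores <- as.numeric(x_scores); a_scores <- as.numeric(a_scores)
  if (any(c(x_scores, a_scores) != round(c(x_scores, a_scores)))) {
    stop("scores must be integers")
  }
  if (is.unsorted(x_scores, strictly = TRUE) ||
      is.unsorted(a_scores, strictly = TRUE)) {
    stop("score grids must be strictly increasing")
  }
  if (is.null(probs)) {
    if (is.null(counts)) stop("either probs or counts must be supplied")
    probs <- counts / sum(counts)
  }
  probs <- as.matrix(probs)
  if (!all(dim(probs) == c(length(x_scores), length(a_scores)))) {
    stop("probs must be a J x L matrix matching the score grids")
  }
  if (any(probs < 0)) {
    if (min(probs) > -1e-8) probs[probs < 0] <- 0 else {
      stop("probabilities must be nonnegative")
    }
  }
  dev <- abs(sum(probs) - 1)
  if (dev >= 1e-8) stop("probabilities must sum to 1 (deviation ", dev, ")")
  if (dev > 1e-10) probs <- probs / sum(probs)
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (any(counts < 0) || any(counts != round(counts))) {
      stop("counts must be nonnegative integers")
    }
    if (is.null(n)) n <- sum(counts)
  }
  structure(
    list(x_scores = x_scores, a_scores = a_scores, probs = probs,
         counts = counts, n = if (is.null(n)) NA_real_ else as.numeric(n)),
    class = "biv_table"
  )
}

#' @export
print.biv_table <- function(x, ...) {
  cat("<biv_table> ", length(x$x_scores), " x ", length(x$a_scores),
      " joint score grid",
      if (!is.na(x$n)) paste0(", n = ", x$n), "\n", sep = "")
  invisible(x)
}

#' Marginal distributions of a bivariate score table
#'
#' @param tab A [biv_table()].
#' @param margin `"x"` for the test-score margin (row sums) or `"a"` for
#'   the anchor margin (column sums).
#' @return A [score_dist()] carrying marginal counts when present.
#' @export
biv_margin <- function(tab, margin = c("x", "a")) {
  margin <- match.arg(margin)
  if (margin == "x") {
    score_dist(tab$x_scores, probs = rowSums(tab$probs),
               counts = if (!is.null(tab$counts)) rowSums(tab$counts),
               n = tab$n)
  } else {
    score_dist(tab$a_scores, probs = colSums(tab$probs),
               counts = if (!is.null(tab$counts)) colSums(tab$counts),
               n = tab$n)
  }
}
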