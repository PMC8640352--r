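# Readers and writers for delimited score-frequency tables.
#
# Univariate schema: columns (score, count); bivariate schema:
# (x_score, a_score, count). Header required; comma-separated for .csv,
# tab-separated otherwise. Missing interior scores are padded with zero
# counts so the grid is always the full integer range.

.read_delim_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, header = TRUE, check.names = FALSE)
}

.check_int_col <- function(v, name, path) {
  bad <- which(!is.finite(v) | v != round(v))
  if (length(bad)) {
    stop("non-integer ", name, " in ", path, " at line ", bad[1] + 1)
  }
}

#' Read a score frequency table
#'
#' Reads a two-column (score, count) file into a [score_dist()] or a
#' three-column (x_score, a_score, count) file into a [biv_table()].
#' Scores missing from the file inside the observed range are filled in
#' with zero counts.
#'
#' @param path Path to a TSV (or `.csv`) file with a header row.
#' @return A [score_dist()] or [biv_table()] with counts.
#' @export
read_frequency_table <- function(path) {
  df <- .read_delim_auto(path)
  if (!ncol(df) %in% 2:3) {
    stop("expected 2 columns (score, count) or 3 (x_score, a_score, count), ",
         "got ", ncol(df), " in ", path)
  }
  for (j in seq_len(ncol(df))) {
    df[[j]] <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(df[[j]])) {
      stop("malformed value in ", path, " at line ",
           which(is.na(df[[j]]))[1] + 1)
    }
  }
  cnt <- df[[ncol(df)]]
  .check_int_col(cnt, "count", path)
  if (any(cnt < 0)) {
    stop("negative count in ", path, " at line ", which(cnt < 0)[1] + 1)
  }
  if (ncol(df) == 2) {
    .check_int_col(df[[1]], "score", path)
    if (anyDuplicated(df[[1]])) {
      stop("duplicate score row in ", path, " at line ",
           which(duplicated(df[[1]]))[1] + 1)
    }
    grid <- seq(min(df[[1]]), max(df[[1]]))
    counts <- integer(length(grid))
    counts[match(df[[1]], grid)] <- cnt
    score_dist(grid, counts = counts)
  } else {
    .check_int_col(df[[1]], "x_score", path)
    .check_int_col(df[[2]], "a_score", path)
    if (anyDuplicated(df[, 1:2])) {
      stop("duplicate (x_score, a_score) row in ", path, " at line ",
           which(duplicated(df[, 1:2]))[1] + 1)
    }
    xg <- seq(min(df[[1]]), max(df[[1]]))
    ag <- seq(min(df[[2]]), max(df[[2]]))
    m <- matrix(0, length(xg), length(ag))
    m[cbind(match(df[[1]], xg), match(df[[2]], ag))] <- cnt
    biv_table(xg, ag, counts = m)
  }
}

#' Write a score frequency table
#'
#' Inverse of [read_frequency_table()]; writes counts when present,
#' otherwise errors (probabilities alone are not a frequency table).
#'
#' @param x A [score_dist()] or [biv_table()] with counts.
#' @param path Output path (`.csv` for comma-separated, else tabs).
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (inherits(x, "score_dist")) {
    if (is.null(x$counts)) stop("no counts to write")
    df <- data.frame(score = x$scores, count = x$counts)
  } else if (inherits(x, "biv_table")) {
    if (is.null(x$counts)) stop("no counts to write")
    df <- data.frame(
      x_score = rep(x$x_scores, times = length(x$a_scores)),
      a_score = rep(x$a_scores, each = length(x$x_scores)),
      count = as.numeric(x$counts)
    )
  } else stop("x must be a score_dist or biv_table")
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
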