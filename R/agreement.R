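#' Cohen's kappa with optional disagreement weighting
#'
#' Chance-corrected agreement between two raters:
#' `kappa = 1 - (observed weighted disagreement) / (expected weighted
#' disagreement)`. Weights are `0/1` (unweighted), `|i - j|` (linear), or
#' `(i - j)^2` (quadratic) over the ordered category indices.
#'
#' @param r1,r2 Equal-length categorical vectors (factors, characters, or
#'   integers).
#' @param weighting `"none"` (default), `"linear"`, or `"quadratic"`.
#' @param levels Optional ordered category levels; defaults to the sorted
#'   union of observed values.
#' @return List of class `"kappa_stat"`: `kappa`, `weighting`, `po`, `pe`
#'   (weighted observed/expected disagreement), `degenerate` (`TRUE` when
#'   expected disagreement is zero and kappa is undefined).
#' @export
cohens_kappa <- function(r1, r2, weighting = c("none", "linear", "quadratic"),
                         levels = NULL) {
  weighting <- match.arg(weighting)
  if (length(r1) != length(r2)) stop("ratings must be paired")
  ok <- !is.na(r1) & !is.na(r2)
  r1 <- r1[ok]; r2 <- r2[ok]
  if (length(r1) == 0L) stop("no complete rating pairs")
  if (is.null(levels)) levels <- sort(unique(c(as.character(r1), as.character(r2))))
  f1 <- factor(as.character(r1), levels = levels)
  f2 <- factor(as.character(r2), levels = levels)
  k <- length(levels)
  tab <- table(f1, f2) / length(f1)
  idx <- seq_len(k)
  w <- switch(weighting,
              none = 1 - diag(k),
              linear = abs(outer(idx, idx, "-")),
              quadratic = outer(idx, idx, "-")^2)
  po <- sum(w * tab)
  pe <- sum(w * outer(rowSums(tab), colSums(tab)))
  degenerate <- pe == 0
  structure(list(kappa = if (degenerate) NA_real_ else 1 - po / pe,
                 weighting = weighting, po = po, pe = pe,
                 degenerate = degenerate),
            class = "kappa_stat")
}

#' @export
print.kappa_stat <- function(x, ...) {
  if (x$degenerate) {
    cat("kappa undefined (expected disagreement is zero)\n")
  } else {
    cat(sprintf("kappa (%s) = %.3f\n", x$weighting, x$kappa))
  }
  invisible(x)
}

#' Light's kappa: mean pairwise Cohen's kappa over all raters
#'
#' @param ratings Cases x raters matrix or data frame of categorical
#'   ratings (>= 2 raters).
#' @param weighting Passed to [cohens_kappa()].
#' @return List of class `"kappa_stat"` with the mean `kappa`, the
#'   per-pair values in `pairwise`, and `degenerate` if any pair was.
#' @export
lights_kappa <- function(ratings, weighting = c("none", "linear", "quadratic")) {
  weighting <- match.arg(weighting)
  m <- as.matrix(ratings)
  if (ncol(m) < 2L) stop("need at least 2 raters")
  levels <- sort(unique(as.character(m[!is.na(m)])))
  pairs <- utils::combn(ncol(m), 2L)
  kv <- apply(pairs, 2L, function(p) {
    cohens_kappa(m[, p[1L]], m[, p[2L]], weighting, levels = levels)$kappa
  })
  structure(list(kappa = mean(kv), weighting = weighting,
                 pairwise = kv, degenerate = any(is.na(kv)),
                 po = NA_real_, pe = NA_real_),
            class = "kappa_stat")
}

#' Intraclass correlation, two-way random, absolute agreement, single measures
#'
#' ICC(A,1) in the McGraw & Wong nomenclature, estimated from the two-way
#' ANOVA mean squares (cases, raters, residual) with an F-based 95%
#' confidence interval. Rows with any missing rating are dropped
#' (listwise) and the number dropped is reported.
#'
#' @param ratings Cases x raters numeric matrix or data frame (>= 2 of
#'   each).
#' @return List of class `"icc_stat"`: `icc`, `ci_low`, `ci_high`, `n`,
#'   `k`, `n_dropped`, and the mean squares.
#' @export
icc_2way_single <- function(ratings) {
  m <- as.matrix(ratings)
  storage.mode(m) <- "double"
  complete <- stats::complete.cases(m)
  n_dropped <- sum(!complete)
  m <- m[complete, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 cases and 2 raters")
  grand <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  msr <- k * sum((rowm - grand)^2) / (n - 1)            # cases
  msc <- n * sum((colm - grand)^2) / (k - 1)            # raters
  sse <- sum((m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  # F-based CI (McGraw & Wong case 2A, single measures)
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(0.975, n - 1, v)
  fu <- stats::qf(0.975, v, n - 1)
  lo <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  structure(list(icc = icc, ci_low = lo, ci_high = hi, n = n, k = k,
                 n_dropped = n_dropped, msr = msr, msc = msc, mse = mse),
            class = "icc_stat")
}

#' @export
print.icc_stat <- function(x, ...) {
  cat(sprintf("ICC(2-way random, absolute agreement, single) = %.3f (95%% CI %.3f-%.3f), n=%d cases x %d raters%s\n",
              x$icc, x$ci_low, x$ci_high, x$n, x$k,
              if (x$n_dropped > 0) sprintf(" (%d incomplete case(s) dropped)", x$n_dropped) else ""))
  invisible(x)
}

#' Verbal interpretation of an agreement coefficient
#'
#' Standard interpretation bands: for kappa, poor (<= 0), slight
#' (0.01-0.20), fair (0.21-0.40), moderate (0.41-0.60), substantial
#' (0.61-0.80), almost perfect (0.81-1.00); for ICC, poor (< 0.40), fair
#' (0.40-0.59), good (0.60-0.74), excellent (0.75-1.00).
#'
#' @param value Coefficient in \[-1, 1\].
#' @param scale `"kappa"` or `"icc"`.
#' @return Band label string.
#' @export
interpret_agreement <- function(value, scale = c("kappa", "icc")) {
  scale <- match.arg(scale)
  if (is.na(value) || value < -1 || value > 1) stop("value must be in [-1, 1]")
  if (scale == "kappa") {
    if (value <= 0) "poor"
    else if (value <= 0.20) "slight"
    else if (value <= 0.40) "fair"
    else if (value <= 0.60) "moderate"
    else if (value <= 0.80) "substantial"
    else "almost perfect"
  } else {
    if (value < 0.40) "poor"
    else if (value < 0.60) "fair"
    else if (value < 0.75) "good"
    else "excellent"
  }
}

#' Count cases on which raters reach consensus
#'
#' A case counts when at least `min_agree` raters assigned the same
#' category.
#'
#' @param ratings Cases x raters categorical matrix or data frame.
#' @param min_agree Minimum number of agreeing raters.
#' @return Integer count of consensus cases.
#' @export
consensus_count <- function(ratings, min_agree) {
  m <- as.matrix(ratings)
  sum(apply(m, 1L, function(row) {
    row <- row[!is.na(row)]
    if (length(row) == 0L) return(FALSE)
    max(table(row)) >= min_agree
  }))
}
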