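# Self-contained statistical primitives shared by all analysis stages.
# These are deliberately implemented in-package (rather than wrapping the
# corresponding base R tests) so that each can be validated against an
# independent oracle; stats::fisher.test and cor(method = "spearman") are
# used only as cross-checks in the test suite.

#' Two-sided Fisher exact test for a 2x2 contingency table
#'
#' Computes the exact two-sided p-value under the conventional
#' probability-mass definition: the sum of hypergeometric probabilities of
#' all tables with the observed margins whose probability does not exceed
#' that of the observed table. A relative tolerance on the comparison
#' absorbs floating-point noise among tied table probabilities.
#'
#' The table layout follows the enrichment-scan convention used throughout
#' the package: `a` = in-group and target, `b` = in-group and non-target,
#' `c` = out-group and target, `d` = out-group and non-target.
#'
#' @param a,b,c,d Non-negative integer cell counts. Alternatively `a` may be
#'   a length-4 vector or 2x2 matrix `(a, b, c, d)`.
#' @param rel_tol Relative tolerance used when comparing table probabilities
#'   to the observed table's probability.
#' @return The two-sided p-value in `(0, 1]`.
#' @examples
#' fisher_exact_two_sided(5, 5, 5, 5)   # most probable table -> 1
#' fisher_exact_two_sided(1, 9, 11, 3)
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL,
                                   rel_tol = 1e-7) {
  if (is.null(b)) {
    x <- as.integer(a)
    if (length(x) != 4L) stopf("expected 4 cell counts, got %d", length(x))
    a <- x[1L]; b <- x[2L]; c <- x[3L]; d <- x[4L]
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stopf("contingency cells must be non-negative counts")
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    stopf("Fisher test undefined: a zero row or column margin")
  }
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, r2, c1)
  p_obs <- probs[a - lo + 1L]
  p <- sum(probs[probs <= p_obs * (1 + rel_tol)])
  min(p, 1)
}

#' Bonferroni familywise rejection
#'
#' Rejects hypothesis `i` iff `pvals[i] <= alpha / m` where `m` is the
#' number of tests in the scan. The boundary is inclusive.
#'
#' @param pvals Numeric vector of raw p-values (one scan).
#' @param alpha Familywise error level; default 0.01.
#' @return Logical vector of rejections (empty input gives empty output).
#' @export
bonferroni_reject <- function(pvals, alpha = 0.01) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stopf("alpha must be a single value in (0, 1)")
  }
  m <- length(pvals)
  if (m == 0L) return(logical(0))
  !is.na(pvals) & pvals <= alpha / m
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the supplied observations with replacement and returns the
#' percentile interval of the statistic. The resampling unit is whatever is
#' passed in: callers that bootstrap over publications pass one value (or
#' row index) per publication.
#'
#' @param x Numeric (or logical) sample; must be nonempty.
#' @param statistic Either one of `"mean"`/`"share"` (a share is the mean of
#'   a 0/1 indicator) or a function mapping a resample to a single number.
#' @param level Interval level in (0, 1); default 0.95.
#' @param n_boot Number of bootstrap replicates; default 1000.
#' @param seed Optional integer seed; the caller's RNG stream is preserved.
#' @return An object of class `genelit_boot`: list with `point`, `lo`, `hi`,
#'   `level`, `n_boot`, `seed`, and `point_outside` (TRUE when the full-sample
#'   statistic falls outside the percentile interval, which can happen for
#'   skewed statistics and is flagged rather than treated as an error).
#' @export
bootstrap_ci <- function(x, statistic = "mean", level = 0.95, n_boot = 1000L,
                         seed = NULL) {
  if (length(x) == 0L) stopf("bootstrap sample is empty")
  if (n_boot < 1L) stopf("n_boot must be a positive integer")
  if (level <= 0 || level >= 1) stopf("level must be in (0, 1)")
  fast_mean <- is.character(statistic) && statistic %in% c("mean", "share")
  f <- if (fast_mean) {
    function(v) mean(v)
  } else if (is.function(statistic)) {
    statistic
  } else {
    stopf("statistic must be 'mean', 'share', or a function")
  }
  x <- as.numeric(x)
  n <- length(x)
  reps <- with_seed(seed, {
    if (fast_mean) {
      # one resampling matrix; rowMeans is the statistic
      idx <- sample.int(n, n * n_boot, replace = TRUE)
      rowMeans(matrix(x[idx], nrow = n_boot))
    } else {
      vapply(seq_len(n_boot),
             function(i) f(x[sample.int(n, n, replace = TRUE)]),
             numeric(1))
    }
  })
  point <- f(x)
  qs <- stats::quantile(reps, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7, na.rm = TRUE)
  structure(
    list(point = point, lo = qs[1L], hi = qs[2L], level = level,
         n_boot = as.integer(n_boot), seed = seed,
         point_outside = is.finite(point) && (point < qs[1L] || point > qs[2L])),
    class = "genelit_boot")
}

#' @export
print.genelit_boot <- function(x, ...) {
  cat(sprintf("bootstrap %g%% CI: %.6g [%.6g, %.6g] (n_boot = %d)\n",
              100 * x$level, x$point, x$lo, x$hi, x$n_boot))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average (mid-) ranks for ties, computed as the
#' Pearson correlation of the rank vectors.
#'
#' @param x,y Paired numeric samples of equal length, at least 3 pairs.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("need at least 3 complete pairs")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) stopf("correlation undefined for a constant vector")
  sum(dx * dy) / (sx * sy)
}

#' Within-cohort midrank percentile
#'
#' Percentile of `value` within `cohort` using the midrank convention:
#' `100 * (number strictly below + half the ties) / cohort size`. Ties are
#' split symmetrically, so the "top 5 percent" flag is stable under ties and
#' the percentile is invariant under any strictly monotone transform of the
#' cohort.
#'
#' @param value A single count (for the scalar form).
#' @param cohort Numeric vector of all values of the same publication-year
#'   cohort (including the value's own publication).
#' @return Percentile in `[0, 100]`.
#' @seealso [cohort_percentiles()] for the vectorized self-percentile form.
#' @export
cohort_percentile <- function(value, cohort) {
  if (length(cohort) == 0L) stopf("cohort is empty")
  100 * (sum(cohort < value) + 0.5 * sum(cohort == value)) / length(cohort)
}

#' Midrank percentile of every member within its own cohort
#'
#' @param x Numeric vector (one cohort).
#' @return Numeric vector of percentiles, same length as `x`.
#' @export
cohort_percentiles <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  100 * (rank(x, ties.method = "average") - 0.5) / length(x)
}
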