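# Condition-contrast statistics ----------------------------------------------

#' Two-sample proportions Z-test
#'
#' Tests whether two proportions (e.g. decoder accuracies, or fractions of
#' untuned neurons) came from the same binomial distribution. The pooled
#' proportion is weighted by the sample sizes, `p = (p1 n1 + p2 n2) /
#' (n1 + n2)`, the standard error is `sqrt(p (1 - p) (1/n1 + 1/n2))`, and
#' `Z = (p1 - p2) / SE` with a two-sided normal p-value.
#'
#' @param p1,n1 First proportion and its sample size.
#' @param p2,n2 Second proportion and its sample size.
#' @return A `prop_z` list: `p1`, `p2`, `n1`, `n2`, `pooled`, `se`, `z`,
#'   `p_value`.
#' @export
two_proportion_ztest <- function(p1, n1, p2, n2) {
  check_scalar(p1, "p1", 0, 1)
  check_scalar(p2, "p2", 0, 1)
  check_scalar(n1, "n1", 1)
  check_scalar(n2, "n2", 1)
  pooled <- (p1 * n1 + p2 * n2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1)
    stop("pooled proportion is 0 or 1: Z undefined (SE = 0)", call. = FALSE)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  structure(list(p1 = p1, p2 = p2, n1 = n1, n2 = n2, pooled = pooled,
                 se = se, z = z, p_value = 2 * stats::pnorm(-abs(z))),
            class = "prop_z")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment with enforced monotonicity.
#'
#' @param p Vector of p-values in [0, 1].
#' @param m Number of comparisons in the family (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_field("p", "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH", n = m)
}

#' Condition contrast by rank-sum or paired t-test
#'
#' Thin adapter over the standard tests, returning a tidy one-row record.
#' For the rank-sum test both the Mann-Whitney U statistic and the rank-sum
#' statistic (`U + n1 (n1 + 1) / 2`, the form reported for small samples)
#' are recorded. A paired t-test on identical samples is undefined and is
#' reported as no difference (p = 1) with an NA statistic.
#'
#' @param x,y Numeric samples.
#' @param test `"rank-sum"` (Wilcoxon/Mann-Whitney, unpaired) or
#'   `"paired-t"`.
#' @param label Optional analysis label carried into the output.
#' @return One-row data.frame: `analysis`, `test`, `statistic`, `ranksum`
#'   (NA for t-tests), `n_x`, `n_y`, `p`.
#' @export
contrast <- function(x, y, test = c("rank-sum", "paired-t"), label = NA) {
  test <- match.arg(test)
  if (length(x) == 0L || length(y) == 0L)
    stop("empty sample", call. = FALSE)
  if (test == "rank-sum") {
    res <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    u <- unname(res$statistic)
    out <- data.frame(analysis = label, test = test, statistic = u,
                      ranksum = u + length(x) * (length(x) + 1) / 2,
                      n_x = length(x), n_y = length(y),
                      p = res$p.value, stringsAsFactors = FALSE)
  } else {
    if (length(x) != length(y))
      stop("paired test requires equal-length samples", call. = FALSE)
    res <- tryCatch(stats::t.test(x, y, paired = TRUE),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$statistic)) {
      out <- data.frame(analysis = label, test = test, statistic = NA_real_,
                        ranksum = NA_real_, n_x = length(x),
                        n_y = length(y), p = 1, stringsAsFactors = FALSE)
    } else {
      out <- data.frame(analysis = label, test = test,
                        statistic = unname(res$statistic), ranksum = NA_real_,
                        n_x = length(x), n_y = length(y), p = res$p.value,
                        stringsAsFactors = FALSE)
    }
  }
  out
}

#' @export
print.prop_z <- function(x, ...) {
  cat(sprintf(
    "<prop_z> p1=%.3f (n=%g) vs p2=%.3f (n=%g): Z=%.3f, p=%.4g\n",
    x$p1, x$n1, x$p2, x$n2, x$z, x$p_value))
  invisible(x)
}
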