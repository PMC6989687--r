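#' Welch's unequal-variance t-test from summary statistics
#'
#' Computes the two-sample Welch t statistic, Welch-Satterthwaite degrees
#' of freedom and two-sided p-value from group means, sample standard
#' deviations (n - 1 denominator) and sizes — the form needed to recompute
#' tests reported in figure legends from printed summaries. Sign
#' convention: group 2 minus group 1.
#'
#' @param mean1,sd1,n1 summary of group 1
#' @param mean2,sd2,n2 summary of group 2
#' @return list: `t`, `df`, `p_two_sided`
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) stop("both SDs are zero; t undefined")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se2 <- v1 + v2
  t <- (mean2 - mean1) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df,
       p_two_sided = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Welch's t-test from raw samples
#'
#' Summarises each sample (mean, n - 1 SD, size) and delegates to
#' [welch_from_summary()].
#'
#' @param x,y numeric vectors, each of length >= 2
#' @return list: `t`, `df`, `p_two_sided` (sign convention: `y` minus `x`)
#' @export
welch_from_raw <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2, !anyNA(x), !anyNA(y))
  welch_from_summary(mean(x), stats::sd(x), length(x),
                     mean(y), stats::sd(y), length(y))
}
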