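# Group-difference tests: Yates chi-square, t-tests, Bonferroni, normality.

#' Yates continuity-corrected chi-square for a 2x2 table
#'
#' chi2 = N * (max(|ad - bc| - N/2, 0))^2 / ((a+b)(c+d)(a+c)(b+d)), df = 1.
#' The continuity-corrected numerator is clamped at zero, so near-null tables
#' give exactly 0.
#'
#' @param a,b first group's hit and miss counts.
#' @param c,d second group's hit and miss counts.
#' @param correct apply the Yates correction (default `TRUE`); `FALSE` gives
#'   the plain Pearson statistic.
#' @return list of class `emostim_test`: `statistic`, `df`, `p`, `kind`.
#' @examples
#' yates_chi_square(13, 7, 19, 1)  # chi2 = 3.91
#' @export
yates_chi_square <- function(a, b, c, d, correct = TRUE) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts %% 1 != 0))
    stop_field("counts", "cell counts must be non-negative integers")
  n <- sum(counts)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    stop_field("margins", "a zero margin leaves the statistic undefined")
  num <- abs(a * d - b * c)
  if (correct) num <- max(num - n / 2, 0)
  stat <- n * num^2 / prod(margins)
  structure(list(statistic = stat, df = 1,
                 p = pchisq(stat, df = 1, lower.tail = FALSE),
                 kind = if (correct) "chi_square_yates" else "chi_square_pearson"),
            class = "emostim_test")
}

#' Reconstruct a 2x2 hit table from printed hit-rate percentages
#'
#' Hit counts are `round(rate/100 * n)`; misses are the complement.
#'
#' @param rate1,rate2 hit rates in percent for the two groups.
#' @param n participants per group (default 20).
#' @return vector `c(a, b, c, d)` suitable for [yates_chi_square()].
#' @export
hit_table_from_rates <- function(rate1, rate2, n = 20L) {
  h1 <- round(rate1 / 100 * n); h2 <- round(rate2 / 100 * n)
  c(a = h1, b = n - h1, c = h2, d = n - h2)
}

#' Two-sample t-test
#'
#' @param x,y numeric samples; for `kind = "paired"` they must have equal
#'   length with rows aligned by the pairing key.
#' @param kind `"independent_pooled"` (equal-variance), `"welch"` or
#'   `"paired"`.
#' @return list of class `emostim_test`: `statistic`, `df`, `p`, `kind`.
#' @export
two_sample_t <- function(x, y, kind = c("independent_pooled", "welch", "paired")) {
  kind <- match.arg(kind)
  if (length(x) < 2L || length(y) < 2L)
    stop_field("samples", "each sample needs n >= 2")
  if (kind == "paired" && length(x) != length(y))
    stop_field("paired", sprintf("length mismatch: %d vs %d", length(x), length(y)))
  if (kind == "paired") {
    d <- x - y
    if (max(abs(d)) == 0)
      return(structure(list(statistic = 0, df = length(d) - 1, p = 1,
                            kind = "paired_t"), class = "emostim_test"))
    if (sd(d) < 1e-10 * max(abs(d)))
      stop_field("variance", "zero variance of paired differences")
  } else if (var(x) == 0 && var(y) == 0) {
    stop_field("variance", "zero variance in both samples")
  }
  ht <- t.test(x, y, paired = kind == "paired",
               var.equal = kind == "independent_pooled")
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 kind = if (kind == "paired") "paired_t" else "independent_t"),
            class = "emostim_test")
}

#' t statistic from summary statistics
#'
#' Pooled-variance or Welch t from means, SDs and sample sizes, for comparing
#' groups reported only as summaries.
#'
#' @param m1,sd1,n1,m2,sd2,n2 group summaries.
#' @param kind `"independent_pooled"` or `"welch"`.
#' @return list of class `emostim_test`.
#' @export
t_from_summary <- function(m1, sd1, n1, m2, sd2, n2,
                           kind = c("independent_pooled", "welch")) {
  kind <- match.arg(kind)
  if (kind == "independent_pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- (sd1^2 / n1 + sd2^2 / n2)^2 /
      ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) stop_field("variance", "zero variance in both samples")
  stat <- (m1 - m2) / se
  structure(list(statistic = stat, df = df,
                 p = 2 * pt(abs(stat), df, lower.tail = FALSE),
                 kind = "independent_t"),
            class = "emostim_test")
}

#' @export
print.emostim_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %.4g, p = %.4g\n",
              x$kind, x$statistic, x$df, x$p))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the family size and caps at 1.
#'
#' @param p p-values in \[0, 1\].
#' @param m family size (default `length(p)`).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stop_field("p", "p-values must lie in [0, 1]")
  pmin(1, m * p)
}

#' Shapiro-Wilk normality check
#'
#' @param values numeric vector, n >= 3, non-constant.
#' @param alpha significance level for the pass flag (default 0.05).
#' @return list with `statistic`, `p`, `pass` (`TRUE` if p >= alpha).
#' @export
normality_check <- function(values, alpha = 0.05) {
  if (length(values) < 3L) stop_field("n", "need at least 3 values")
  if (var(values) == 0) stop_field("values", "constant input")
  sw <- shapiro.test(values)
  list(statistic = unname(sw$statistic), p = sw$p.value, pass = sw$p.value >= alpha)
}
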