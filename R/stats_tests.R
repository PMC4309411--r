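#' Statistical test result container
#'
#' Light S3 container used by all compartment comparisons: a named statistic,
#' its value, degrees of freedom and a two-tailed p-value.
#'
#' @param statistic one of "chi2", "chi2_yates", "t", "F".
#' @param value numeric statistic value.
#' @param df integer degrees of freedom (length 1 or 2).
#' @param p two-tailed p-value in [0, 1].
#' @param n integer sample sizes used (optional).
#' @return an object of class \code{compartment_test}.
#' @export
compartment_test <- function(statistic, value, df, p, n = NULL) {
  structure(
    list(statistic = statistic, value = value, df = df, p = p, n = n),
    class = "compartment_test"
  )
}

#' @export
print.compartment_test <- function(x, ...) {
  cat(sprintf(
    "%s = %.4g, df = %s, p = %.4g\n",
    x$statistic, x$value, paste(x$df, collapse = ", "), x$p
  ))
  invisible(x)
}

#' Chi-squared goodness-of-fit test
#'
#' Pearson goodness of fit against externally supplied expected counts
#' (which need not sum to the observed total, matching observed/expected
#' table conventions where expectations come from genome-wide fractions).
#'
#' @param observed non-negative observed counts.
#' @param expected positive expected counts, same length.
#' @return a \code{compartment_test} with statistic \code{chi2}, df = k - 1.
#' @export
chi2_gof <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("observed and expected must have the same length")
  if (any(!is.finite(expected)) || any(expected <= 0))
    stop("all expected counts must be positive")
  if (any(observed < 0)) stop("observed counts must be non-negative")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  compartment_test("chi2", stat, df, p, n = sum(observed))
}

#' 2x2 chi-squared test with Yates continuity correction
#'
#' Expected counts derive from the table margins; the continuity correction
#' term |O - E| - 0.5 is floored at zero. Agrees with
#' \code{stats::chisq.test(correct = TRUE)}.
#'
#' @param tab a 2x2 matrix of non-negative counts with positive margins.
#' @return a \code{compartment_test} with statistic \code{chi2_yates}, df = 1.
#' @export
chi2_2x2_yates <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("tab must be a 2x2 matrix")
  if (any(tab < 0)) stop("counts must be non-negative")
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs <= 0) || any(cs <= 0)) stop("all margins must be positive")
  e <- outer(rs, cs) / sum(tab)
  adj <- pmax(abs(tab - e) - 0.5, 0)
  stat <- sum(adj^2 / e)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  compartment_test("chi2_yates", stat, 1L, p, n = sum(tab))
}

#' Equal-variance two-sample t-test
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return a \code{compartment_test} with statistic \code{t},
#'   df = n_a + n_b - 2, two-tailed p.
#' @export
t_test_ind <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  df <- length(a) + length(b) - 2L
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(compartment_test("t", 0, df, 1, n = c(length(a), length(b))))
    stop("zero variance with unequal means: t undefined")
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  compartment_test("t", unname(tt$statistic), unname(tt$parameter),
                   tt$p.value, n = c(length(a), length(b)))
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition with equal-variance assumption
#' (so that for two groups F equals the square of \code{t_test_ind}).
#'
#' @param groups a list of >= 2 numeric vectors, each of length >= 2.
#' @return a \code{compartment_test} with statistic \code{F} and df = (k-1,
#'   N-k).
#' @export
anova_oneway <- function(groups) {
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs n >= 2")
  n <- vapply(groups, length, 1L)
  k <- length(groups)
  df <- c(k - 1L, sum(n) - k)
  if (all(vapply(groups, stats::var, 1) == 0) &&
      length(unique(vapply(groups, mean, 1))) == 1L) {
    return(compartment_test("F", 0, df, 1, n = n))
  }
  vals <- unlist(groups, use.names = FALSE)
  fac <- factor(rep.int(seq_len(k), n))
  ow <- stats::oneway.test(vals ~ fac, var.equal = TRUE)
  compartment_test("F", unname(ow$statistic), unname(ow$parameter),
                   ow$p.value, n = n)
}
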