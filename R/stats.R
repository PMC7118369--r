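#' Welch's unpaired two-sample t test
#'
#' The t statistic uses the unpooled-variance (Welch) form with
#' Welch-Satterthwaite degrees of freedom and a two-sided p value from the t
#' distribution. When both samples have zero variance: equal means give
#' t = 0, p = 1; unequal means are undefined and flagged degenerate (p NA).
#'
#' @param x,y numeric samples of length >= 2 with finite values.
#' @return A [TestResult-class].
#' @export
welchT <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("welchT: both samples need n >= 2")
  if (!all(is.finite(c(x, y)))) stop("welchT: samples must be finite")
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0) {
    if (mean(x) == mean(y)) {
      return(TestResult("Welch two-sample t test", 0, NA_real_, 1, n1, n2))
    }
    return(TestResult("Welch two-sample t test",
                      sign(mean(x) - mean(y)) * Inf, NA_real_, NA_real_,
                      n1, n2, degenerate = TRUE))
  }
  se2 <- v1 / n1 + v2 / n2
  tStat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tStat), df)
  TestResult("Welch two-sample t test", tStat, df, p, n1, n2)
}

#' Mann-Whitney U test
#'
#' Reports U for the first sample (rank sum of x minus its minimum) with
#' midrank tie handling. The two-sided p value is exact — by full enumeration
#' of the \eqn{\binom{n_1+n_2}{n_1}} rank assignments — when the combined
#' sample size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y non-empty numeric samples.
#' @param exact force exact (`TRUE`) or approximate (`FALSE`) p; default
#'   `NULL` applies the size-12/no-ties rule. Exact with ties is refused.
#' @return A [TestResult-class] (statistic = U of x; df is NA).
#' @export
mannWhitneyU <- function(x, y, exact = NULL) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("mannWhitneyU: samples must be non-empty")
  comb <- c(x, y)
  r <- rank(comb)                      # midranks for ties
  ties <- any(duplicated(comb))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (is.null(exact)) exact <- (n1 + n2 <= 12L) && !ties
  if (exact && ties) stop("mannWhitneyU: exact p is not defined with ties")
  if (exact) {
    sets <- utils::combn(n1 + n2, n1)
    Uall <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    uSmall <- min(U1, n1 * n2 - U1)
    p <- min(1, 2 * mean(Uall <= uSmall))
  } else {
    mu <- n1 * n2 / 2
    nTot <- n1 + n2
    tieTab <- table(comb)
    tieTerm <- sum(tieTab^3 - tieTab) / (nTot * (nTot - 1))
    sigma <- sqrt(n1 * n2 / 12 * (nTot + 1 - tieTerm))
    z <- U1 - mu
    z <- z - sign(z) * 0.5             # continuity correction
    p <- if (sigma == 0) 1 else min(1, 2 * stats::pnorm(-abs(z) / sigma))
  }
  TestResult(sprintf("Mann-Whitney U test (%s)",
                     if (exact) "exact" else "normal approximation"),
             U1, NA_real_, p, n1, n2)
}

#' Paired t test
#'
#' One-sample t test on the elementwise differences with a two-sided p. All
#' differences zero gives t = 0, p = 1; a constant non-zero difference has
#' zero variance, so the statistic is infinite — it is flagged degenerate and
#' the p value reported as the smallest positive double rather than 0.
#'
#' @param x,y paired numeric samples of equal length >= 2.
#' @return A [TestResult-class].
#' @export
pairedT <- function(x, y) {
  if (length(x) != length(y)) stop("pairedT: samples must be paired (equal length)")
  n <- length(x)
  if (n < 2L) stop("pairedT: need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(TestResult("Paired t test", 0, n - 1, 1, n, n))
    }
    return(TestResult("Paired t test", sign(mean(d)) * Inf, n - 1,
                      .Machine$double.xmin, n, n, degenerate = TRUE))
  }
  tStat <- mean(d) / (stats::sd(d) / sqrt(n))
  p <- 2 * stats::pt(-abs(tStat), n - 1)
  TestResult("Paired t test", tStat, n - 1, p, n, n)
}

#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by sqrt(n); the
#' spread statistic used for "mean +/- SEM" reporting.
#'
#' @param values numeric sample of length >= 2.
#' @return The SEM.
#' @examples
#' sem(c(0.8, 1.0))  # 0.1
#' @export
sem <- function(values) {
  n <- length(values)
  if (n < 2L) stop("sem: need at least 2 values")
  stats::sd(values) / sqrt(n)
}

#' Shapiro-Wilk normality helper (reporting only)
#'
#' Thin wrapper over [stats::shapiro.test()] provided for report annotation;
#' it plays no role in choosing which test the pipeline runs — the caller
#' decides that.
#'
#' @param values numeric sample (3 <= n <= 5000).
#' @return A list with `statistic` and `pValue`.
#' @export
normalityCheck <- function(values) {
  res <- stats::shapiro.test(values)
  list(statistic = unname(res$statistic), pValue = res$p.value)
}
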