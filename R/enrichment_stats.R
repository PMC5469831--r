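#' @importFrom stats phyper dhyper binom.test fisher.test p.adjust ks.test
#'   chisq.test pchisq cor quantile lm coef predict var sd rnorm runif
#'   rlnorm median optimize
NULL

.testResult <- function(statistic, p, method, ...) {
  p <- min(max(p, .Machine$double.xmin), 1)
  c(list(statistic = statistic, p_value = p, method = method), list(...))
}

#' Two-tailed hypergeometric test with fold change
#'
#' Draw `n` genes from an urn of `N` with `K` marked; `k` marked observed.
#' The two-tailed p-value is the doubled smaller tail,
#' `min(1, 2 * min(P[X <= k], P[X >= k]))`, and the fold change is
#' observed/expected, `(k/n) / (K/N)`.
#'
#' @param k Marked genes in the category.
#' @param K Marked genes overall.
#' @param n Category size.
#' @param N Total genes.
#' @return List with `statistic` (fold), `p_value`, `method`, `fold`,
#'   `expected`.
#' @export
hypergeomTwoTailed <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= 1, k <= n, k <= K, K <= N, n <= N)
  if (K == 0) stop("fold change undefined: no marked genes (K = 0)")
  lower <- phyper(k, K, N - K, n)
  upper <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p <- min(1, 2 * min(lower, upper))
  expected <- n * K / N
  fold <- if (n > 0) (k / n) / (K / N) else NA_real_
  .testResult(fold, p, "two-tailed hypergeometric (doubled tail)",
              fold = fold, expected = expected)
}

#' Exact two-sided binomial test
#'
#' Exact two-sided p-value summing all outcomes whose point probability
#' does not exceed that of the observed count (the construction used by
#' `binom.test`), via `stats::binom.test`.
#'
#' @param x Successes.
#' @param n Trials (> 0).
#' @param p0 Null success probability.
#' @return List with `statistic` (x), `p_value`, `method`, `fold`.
#' @export
binomialTwoSided <- function(x, n, p0) {
  if (n <= 0) stop("binomial test needs n > 0")
  bt <- binom.test(x, n, p = p0, alternative = "two.sided")
  .testResult(x, bt$p.value, "exact binomial (two-sided)",
              fold = (x / n) / p0)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by hypergeometric enumeration of all tables with the
#' observed margins whose probability does not exceed the observed
#' table's, via `stats::fisher.test`.
#'
#' @param table 2x2 integer matrix.
#' @return List with `statistic` (odds ratio estimate), `p_value`, `method`.
#' @export
fisherExact2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  ft <- fisher.test(table)
  .testResult(unname(ft$estimate), ft$p.value, "Fisher exact (two-sided)")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control; never decreases a p-value, capped
#' at 1.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted vector, same order as input.
#' @export
bhAdjust <- function(p) p.adjust(p, method = "BH")

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic p-value; tie warnings
#' from the underlying test are suppressed (coverage-derived quantities
#' tie routinely).
#'
#' @param a,b Numeric samples.
#' @return List with `statistic` (D), `p_value`, `method`.
#' @export
ksTwoSample <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  kt <- suppressWarnings(ks.test(a, b))
  .testResult(unname(kt$statistic), kt$p.value,
              "two-sample Kolmogorov-Smirnov")
}

#' Global chi-squared test with post-hoc adjusted standardized residuals
#'
#' Pearson chi-squared on an r x c contingency table, plus the adjusted
#' standardized residual for every cell,
#' `(O - E) / sqrt(E (1 - rowsum/N) (1 - colsum/N))`, which is
#' approximately standard normal under independence and localizes which
#' cells drive a significant global test.
#'
#' @param table Integer matrix (>= 2x2) of counts.
#' @return List with `statistic` (X-squared), `p_value`, `method`,
#'   `expected`, `residuals` (the adjusted standardized residuals).
#' @export
chisqPosthoc <- function(table) {
  stopifnot(is.matrix(table), nrow(table) >= 2L, ncol(table) >= 2L,
            all(table >= 0), sum(table) > 0)
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  .testResult(unname(ct$statistic), ct$p.value,
              "Pearson chi-squared with adjusted standardized residuals",
              expected = ct$expected, residuals = ct$stdres,
              df = unname(ct$parameter))
}
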