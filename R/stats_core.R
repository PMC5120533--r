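#' Exact statistical primitives
#'
#' hybridexpr's test machinery rests on three primitives used by every
#' downstream stage: a two-sided exact binomial test (allelic-balance null),
#' Fisher's exact test on 2x2 tables (count comparisons between samples),
#' and Benjamini-Hochberg FDR adjustment. Both exact tests use the
#' minimum-likelihood two-sided convention: the p-value sums the
#' probabilities of all outcomes no more likely than the observed one.
#'
#' @name stats_core
NULL

# Relative tolerance when comparing point probabilities, matching the
# convention of the classical exact-test implementations: outcomes whose
# probability exceeds the observed one by less than 1e-7 relative are still
# counted as "at most as likely".
.REL_ERR <- 1 + 1e-7

#' Two-sided exact binomial test (minimum-likelihood method)
#'
#' P-value is the sum of `dbinom(i, n, p0)` over all outcomes `i` whose
#' point probability does not exceed that of the observed `k`. Vectorised
#' over `k` and `n`.
#'
#' @param k Integer vector of success counts, `0 <= k <= n`.
#' @param n Integer vector of trial counts, `n >= 1`. Recycled against `k`.
#' @param p0 Null success probability, a single value in (0, 1).
#' @return Numeric vector of two-sided p-values in (0, 1].
#' @examples
#' binomial_two_sided(8, 10)          # 112/1024
#' binomial_two_sided(0, 10)          # 2/1024
#' @export
binomial_two_sided <- function(k, n, p0 = 0.5) {
  if (length(p0) != 1L || is.na(p0) || p0 <= 0 || p0 >= 1)
    stop("'p0' must be a single value strictly between 0 and 1")
  kn <- .recycle2(k, n)
  k <- kn[[1L]]; n <- kn[[2L]]
  if (anyNA(k) || anyNA(n)) stop("'k' and 'n' must not contain NA")
  if (any(n < 1)) stop("'n' must be >= 1")
  if (any(k < 0) || any(k > n)) stop("'k' must satisfy 0 <= k <= n")
  vapply(seq_along(k), function(i) {
    pmf <- stats::dbinom(0:n[i], n[i], p0)
    min(1, sum(pmf[pmf <= pmf[k[i] + 1L] * .REL_ERR]))
  }, numeric(1))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value for the table `rbind(c(a, b), c(c, d))` by hypergeometric
#' enumeration: all tables with the observed margins whose probability does
#' not exceed the observed table's are summed. Vectorised over the four cells.
#'
#' @param a,b,c,d Non-negative integer cell counts (first row `a`, `b`;
#'   second row `c`, `d`). Recycled to a common length.
#' @return Numeric vector of two-sided p-values in (0, 1].
#' @examples
#' fisher_exact_2x2(10, 0, 0, 10)     # 2/choose(20, 10)
#' fisher_exact_2x2(5, 5, 5, 5)       # 1
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- .recycle4(a, b, c, d)
  a <- cells[[1L]]; b <- cells[[2L]]; c <- cells[[3L]]; d <- cells[[4L]]
  if (anyNA(a) || anyNA(b) || anyNA(c) || anyNA(d))
    stop("cell counts must not contain NA")
  if (any(a < 0) || any(b < 0) || any(c < 0) || any(d < 0))
    stop("cell counts must be non-negative")
  if (any(a + b + c + d == 0)) stop("at least one margin must be positive")
  vapply(seq_along(a), function(i) {
    r1 <- a[i] + b[i]          # row margins
    c1 <- a[i] + c[i]          # first column margin
    tot <- r1 + c[i] + d[i]
    lo <- max(0, c1 - (tot - r1))
    hi <- min(r1, c1)
    x <- lo:hi
    pmf <- stats::dhyper(x, r1, tot - r1, c1)
    min(1, sum(pmf[pmf <= stats::dhyper(a[i], r1, tot - r1, c1) * .REL_ERR]))
  }, numeric(1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1,
#' where `m` counts the non-missing p-values. `NA` entries (untestable genes)
#' are passed through as `NA` and do not enter `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("'p' must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m == 0L) return(q)
  ps <- p[ok]
  o <- order(ps, decreasing = TRUE)
  ro <- order(o)
  q[ok] <- pmin(1, cummin(ps[o] * m / (m:1)))[ro]
  q
}

#' Build a TestResult data frame
#'
#' Bundles an effect statistic with its p-value; q-values are filled in by
#' [finalize_tests()] once the whole family of tests is available.
#'
#' @param statistic Effect measure on the log2 scale.
#' @param p_value Two-sided p-value (NA for untestable cases).
#' @return A data frame with columns `statistic`, `p_value`, `q_value`,
#'   `significant` (the latter two NA until finalized).
#' @seealso [finalize_tests()]
#' @export
test_result <- function(statistic, p_value) {
  data.frame(statistic = statistic, p_value = p_value,
             q_value = NA_real_, significant = NA)
}

#' Finalize a family of tests with FDR adjustment
#'
#' @param tests A data frame from [test_result()] covering one test family
#'   (e.g. all genes of one comparison).
#' @param alpha Q-value significance threshold (default 0.05).
#' @return The data frame with `q_value` and `significant` filled in
#'   (`significant` is `q_value < alpha`).
#' @export
finalize_tests <- function(tests, alpha = 0.05) {
  .check_alpha(alpha)
  tests$q_value <- bh_adjust(tests$p_value)
  tests$significant <- !is.na(tests$q_value) & tests$q_value < alpha
  tests
}

.check_alpha <- function(alpha) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single value strictly between 0 and 1")
  invisible(alpha)
}

.recycle2 <- function(x, y) {
  n <- max(length(x), length(y))
  list(rep_len(x, n), rep_len(y, n))
}

.recycle4 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  list(rep_len(a, n), rep_len(b, n), rep_len(c, n), rep_len(d, n))
}
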