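#' Exact two-sided binomial test p-values
#'
#' Two-sided p-value by the minimum-likelihood method: the sum of
#' probabilities of all outcomes no more probable than the observed one,
#' under X ~ Binomial(n, p0). Vectorized over `k` and `n`; delegates to
#' [stats::binom.test()], which implements exactly this definition.
#'
#' @param k successes (vector).
#' @param n trials (vector or scalar), all >= 1.
#' @param p0 null success probability (default 0.5; equalized library totals
#'   make 0.5 the consistent null for both strain and allele comparisons).
#' @return numeric vector of p-values.
#' @export
binom_two_sided <- function(k, n, p0 = 0.5) {
  if (length(n) == 1L) n <- rep(n, length(k))
  stopifnot(length(k) == length(n))
  if (any(n < 1)) stop("n must be >= 1")
  if (any(k < 0 | k > n)) stop("k must be in [0, n]")
  vapply(seq_along(k),
         function(i) stats::binom.test(k[i], n[i], p = p0)$p.value,
         numeric(1))
}

# vectorized G statistic and p for 2x2 tables given as four cell vectors
# (rows = molecule or strain, columns = the compared pair). Cells with O = 0
# contribute 0. Tables with a zero row or column margin are degenerate:
# G = 0, p = 1.
g_test_cells <- function(a1, a2, b1, b2) {
  r1 <- a1 + a2; r2 <- b1 + b2
  c1 <- a1 + b1; c2 <- a2 + b2
  n <- r1 + r2
  degenerate <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  term <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  g <- 2 * (term(a1, r1 * c1 / n) + term(a2, r1 * c2 / n) +
              term(b1, r2 * c1 / n) + term(b2, r2 * c2 / n))
  g[degenerate] <- 0
  p <- stats::pchisq(g, df = 1L, lower.tail = FALSE)
  p[degenerate] <- 1
  list(statistic = g, p.value = p, degenerate = degenerate)
}

#' G-test of independence for a 2x2 table
#'
#' Likelihood-ratio test G = 2 * sum(O * ln(O/E)) with expectations from the
#' row/column margins, compared to a chi-squared distribution with 1 df. No
#' Williams or Yates correction is applied. A table with a zero row or
#' column margin is degenerate and returns p = 1 with a warning.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return list with `statistic`, `p.value`, `df`.
#' @export
g_test_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  if (sum(tab) == 0) stop("all-zero table")
  r <- g_test_cells(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  if (r$degenerate) warning("zero row or column margin; p set to 1")
  list(statistic = r$statistic, p.value = r$p.value, df = 1L)
}

#' Bonferroni correction and raw-scale threshold
#'
#' @param pvals p-values in \[0, 1\].
#' @param alpha family-wise error level.
#' @return list with `adjusted` (min(1, m * p)) and `threshold` (alpha / m on
#'   the raw p scale).
#' @export
bonferroni <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0L) stop("empty p-value vector")
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  list(adjusted = stats::p.adjust(pvals, method = "bonferroni"),
       threshold = alpha / length(pvals))
}

#' Storey q-values
#'
#' False-discovery-rate q-values with the proportion of true nulls pi0
#' estimated by a natural cubic spline (df = 3) through pi0(lambda) over
#' lambda in 0, 0.05, ..., 0.90, evaluated at the largest lambda. With fewer
#' than 100 p-values the spline is unreliable and pi0 is fixed at 1 (with a
#' warning), which reduces to Benjamini-Hochberg-style adjusted p-values.
#' Monotonicity of q in p is enforced by a step-down pass; ties share the
#' largest rank.
#'
#' @param pvals p-values in \[0, 1\].
#' @return numeric vector of q-values, same order as `pvals`, with the
#'   estimated pi0 attached as attribute `"pi0"`.
#' @export
storey_qvalues <- function(pvals) {
  if (!is.numeric(pvals)) stop("non-numeric p-values")
  if (length(pvals) == 0L) stop("empty p-value vector")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must be in [0, 1]")
  m <- length(pvals)
  lambda <- seq(0, 0.9, by = 0.05)
  if (m < 100L) {
    warning("fewer than 100 p-values; pi0 fixed at 1")
    pi0 <- 1
  } else {
    pi0_l <- vapply(lambda, function(l) mean(pvals > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
  }
  r <- rank(pvals, ties.method = "max")
  q <- pi0 * m * pvals / r
  o <- order(pvals, decreasing = TRUE)
  q[o] <- cummin(q[o])
  structure(pmin(q, 1), pi0 = pi0)
}

#' Chi-squared test of equal frequency for two counts
#'
#' Goodness-of-fit test of the observed counts (a, b) against the expected
#' even split (N/2, N/2), 1 df, no continuity correction. The statistic
#' simplifies to (a - b)^2 / (a + b).
#'
#' @param a,b non-negative counts (vectors).
#' @return data.frame with `statistic` and `p.value`.
#' @export
chi2_equal_frequency <- function(a, b) {
  stopifnot(length(a) == length(b), all(a >= 0), all(b >= 0))
  n <- a + b
  if (any(n == 0)) stop("both counts zero")
  stat <- (a - b)^2 / n
  data.frame(statistic = stat,
             p.value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}
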