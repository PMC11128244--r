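#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Conditional exact test with the minimum-likelihood two-sided convention:
#' with margins fixed, the p-value is the sum of hypergeometric probabilities
#' of all tables whose probability does not exceed that of the observed table
#' (up to a 1e-7 relative tolerance, the convention of mainstream exact-test
#' implementations).
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `matrix(c(a, b, c, d), 2, byrow = TRUE)`.
#' @return The two-sided p-value in (0, 1]. An all-zero table returns 1 with
#'   a warning.
#' @export
fisher_exact_two_tailed <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (all(cells == 0)) {
    warning("all-zero table; p = 1 by convention")
    return(1)
  }
  m <- a + b      # row-1 margin
  n <- c + d      # row-2 margin
  k <- a + c      # column-1 margin
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- probs[match(a, support)]
  p <- sum(probs[probs <= obs * (1 + 1e-7)])
  min(p, 1)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at
#' 1, returned in the input order.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Welch's two-sided t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom.
#'
#' @param x,y Numeric samples, each of size >= 2; at least one must have
#'   nonzero variance.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_two_sided <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample must contain at least 2 observations")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    stop("both samples have zero variance")
  }
  fit <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}

#' Sample odds ratio with Haldane-Anscombe correction
#'
#' Display-only odds ratio for a 2x2 table; 0.5 is added to every cell
#' whenever any cell is zero. Never used for p-values.
#'
#' @inheritParams fisher_exact_two_tailed
#' @return The (corrected) sample odds ratio.
#' @export
sample_odds_ratio <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}
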