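# Exact inference from first principles: the hypergeometric Fisher test
# and the exact binomial tail. stats::fisher.test / stats::pbinom are used
# only as independent cross-checks in the test suite.

#' 2x2 contingency table
#'
#' @param a,b,c,d Non-negative integer counts, row-major: `a`,`b` form the
#'   first row and `c`,`d` the second.
#' @param row_labels,col_labels Length-2 character labels.
#' @return A `contingency_2x2` object.
#' @export
contingency_2x2 <- function(a, b, c, d,
                            row_labels = c("row1", "row2"),
                            col_labels = c("col1", "col2")) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_metox("counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop_metox("all-zero contingency table")
  structure(list(a = a, b = b, c = c, d = d,
                 row_labels = row_labels, col_labels = col_labels),
            class = "contingency_2x2")
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
         dimnames = list(x$row_labels, x$col_labels))
}

# log hypergeometric point masses over the support of cell `a` given the
# margins of t
hyper_support <- function(t) {
  r1 <- t$a + t$b; r2 <- t$c + t$d; c1 <- t$a + t$c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  lp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)
  list(xs = xs, lp = lp, r1 = r1, r2 = r2, c1 = c1, n = n)
}

#' Fisher's exact test for a 2x2 table
#'
#' The conditional hypergeometric distribution of the top-left cell given
#' fixed margins is computed in log space from log binomial coefficients.
#' The one-sided p-value is the tail in the observed direction (enrichment
#' if the cell exceeds its conditional expectation, depletion otherwise);
#' the two-sided p-value sums all tables whose point probability does not
#' exceed the observed one (minimum-likelihood convention). Both are
#' always reported. For small tables the tail is additionally returned as
#' an exact integer ratio.
#'
#' @param t A `contingency_2x2`.
#' @return A `fisher_result`: list with `p_one_sided`, `p_two_sided`,
#'   `direction` (`"enrichment"`, `"depletion"` or `"none"`),
#'   `odds_ratio` (sample odds ratio `ad/bc`), and `exact` (list
#'   `numerator`, `denominator` for the one-sided tail when every binomial
#'   coefficient involved is exactly representable as a double, else
#'   `NULL`).
#' @export
fisher_exact <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  h <- hyper_support(t)
  if (h$r1 == 0 || h$r2 == 0 || h$c1 == 0 || h$c1 == h$n) {
    return(structure(list(p_one_sided = 1, p_two_sided = 1,
                          direction = "none",
                          odds_ratio = NaN, exact = NULL),
                     class = "fisher_result"))
  }
  obs <- t$a
  i_obs <- match(obs, h$xs)
  expected <- h$r1 * h$c1 / h$n
  upper <- sum(exp(h$lp[h$xs >= obs]))
  lower <- sum(exp(h$lp[h$xs <= obs]))
  if (obs > expected) {
    direction <- "enrichment"; p1 <- upper; tail_xs <- h$xs[h$xs >= obs]
  } else if (obs < expected) {
    direction <- "depletion"; p1 <- lower; tail_xs <- h$xs[h$xs <= obs]
  } else {
    direction <- "none"; p1 <- min(upper, lower)
    tail_xs <- if (upper <= lower) h$xs[h$xs >= obs] else h$xs[h$xs <= obs]
  }
  # minimum-likelihood two-sided: same relative tolerance as fisher.test
  p2 <- sum(exp(h$lp[h$lp <= h$lp[i_obs] + log(1 + 1e-7)]))
  exact <- NULL
  ways <- choose(h$r1, tail_xs) * choose(h$r2, h$c1 - tail_xs)
  denom <- choose(h$n, h$c1)
  if (all(is.finite(ways)) && is.finite(denom) &&
      denom <= 2^53 && all(ways <= 2^53)) {
    exact <- list(numerator = sum(ways), denominator = denom)
  }
  structure(list(p_one_sided = min(p1, 1), p_two_sided = min(p2, 1),
                 direction = direction,
                 odds_ratio = (t$a * t$d) / (t$b * t$c),
                 exact = exact),
            class = "fisher_result")
}

#' Exact binomial upper tail
#'
#' `P[X >= k]` for `X ~ Binomial(n, p)`, computed as the explicit sum of
#' point masses from log binomial coefficients.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p Success probability.
#' @return Upper-tail probability.
#' @export
binomial_tail <- function(k, n, p) {
  if (k < 0 || k > n || n < 0) stop_metox("require 0 <= k <= n")
  if (p < 0 || p > 1) stop_metox("p must lie in [0, 1]")
  if (k == 0) return(1)
  xs <- k:n
  if (p == 0) return(0)
  if (p == 1) return(1)
  sum(exp(lchoose(n, xs) + xs * log(p) + (n - xs) * log1p(-p)))
}
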