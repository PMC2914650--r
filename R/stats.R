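# Nonparametric statistics used across the analyses.
#
# Conventions, pinned because several two-sided definitions exist:
#  * Spearman: mid-ranks for ties; exact permutation p for n <= 9 without
#    ties, t approximation otherwise.
#  * Wilcoxon rank-sum: exact enumeration when n_a + n_b <= 12 and no
#    ties, normal approximation with tie correction otherwise (no
#    continuity correction in the approximate branch).
#  * Fisher 2x2: two-sided p is the probability-mass rule (sum over
#    tables with the observed margins whose hypergeometric probability
#    does not exceed that of the observed table); the reported odds
#    ratio is the sample OR (a*d)/(b*c), not the conditional MLE.

#' Spearman rank correlation with two-sided p-value
#'
#' Correlation of mid-ranks. For n <= 9 with no ties the p-value is the
#' exact permutation p; otherwise the t approximation on
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} is used. Constant input leaves
#' the correlation undefined and is reported as such rather than an error.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return A `correlation_result`: list with `rho`, `p_value`, `n`,
#'   `method`, and `defined` (FALSE when either input is constant).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop_fmt("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop_fmt("need at least 3 complete pairs, got %d", n)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(structure(list(rho = NA_real_, p_value = NA_real_, n = n,
                          method = "undefined (constant input)",
                          defined = FALSE),
                     class = "correlation_result"))
  }
  rho <- stats::cor(rank(x), rank(y))
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= 9 && !ties) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  structure(list(rho = rho, p_value = min(p, 1), n = n,
                 method = method, defined = TRUE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("Spearman correlation: undefined (constant input), n = %d\n", x$n))
  } else {
    cat(sprintf("Spearman rho = %.4f, p = %.4g (%s), n = %d\n",
                x$rho, x$p_value, x$method, x$n))
  }
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum comparison of two groups
#'
#' Exact enumeration of the rank-sum distribution when
#' `length(a) + length(b) <= 12` and there are no ties; normal
#' approximation with tie correction otherwise. Group medians are
#' reported alongside the p-value.
#'
#' @param a,b numeric vectors, both non-empty.
#' @return A `group_comparison_result`: list with `median_a`, `median_b`,
#'   `p_value`, `n_a`, `n_b`, `method`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L) stop_fmt("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE)
  )
  p <- wt$p.value
  # fully tied pooled sample: zero-variance normal approximation; the
  # data carry no evidence either way
  if (is.nan(p)) p <- 1
  structure(list(median_a = stats::median(a), median_b = stats::median(b),
                 p_value = p, n_a = length(a), n_b = length(b),
                 method = if (exact) "exact enumeration"
                          else "normal approximation, tie-corrected"),
            class = "group_comparison_result")
}

#' @export
print.group_comparison_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: medians %.4g vs %.4g, p = %.4g (n = %d, %d; %s)\n",
              x$median_a, x$median_b, x$p_value, x$n_a, x$n_b, x$method))
  invisible(x)
}

#' Construct a validated 2x2 contingency table
#'
#' Layout: rows are the two groups, columns the yes/no outcome, entries
#' `a, b` (row 1) and `c, d` (row 2).
#'
#' @param a,b,c,d non-negative integer counts, not all zero.
#' @return A `contingency_2x2` object (named integer vector).
#' @export
contingency_2x2 <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round_half_up(v))) {
    stop_fmt("contingency entries must be non-negative integers")
  }
  if (sum(v) == 0) stop_fmt("contingency table must have at least one positive entry")
  structure(as.integer(v), names = names(v), class = "contingency_2x2")
}

#' Fisher's exact test on a 2x2 table with sample odds ratio
#'
#' Two-sided p under the probability-mass rule. The odds ratio is the
#' sample estimate \eqn{(a d)/(b c)}; `Inf` when `b*c == 0` with
#' `a*d > 0`, and undefined (`NaN`) when both products are zero.
#' Row percentages (share of "yes" in each row) are included because the
#' downstream reports quote them.
#'
#' @param tab a `contingency_2x2`, or four counts via `a,b,c,d`.
#' @param a,b,c,d alternative scalar interface.
#' @return A `contingency_result`: list with `odds_ratio`, `p_value`,
#'   `table`, `pct_row1`, `pct_row2` (percent "yes" per row).
#' @export
fisher_exact_2x2 <- function(tab, a, b, c, d) {
  if (missing(tab)) tab <- contingency_2x2(a, b, c, d)
  if (!inherits(tab, "contingency_2x2")) {
    tab <- contingency_2x2(tab[1], tab[2], tab[3], tab[4])
  }
  m <- matrix(as.numeric(tab), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(m)$p.value
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  structure(list(odds_ratio = or, p_value = min(p, 1), table = tab,
                 pct_row1 = 100 * m[1, 1] / sum(m[1, ]),
                 pct_row2 = 100 * m[2, 1] / sum(m[2, ])),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Fisher exact 2x2: OR = %.4g, p = %.4g; yes-share %.1f%% vs %.1f%%\n",
              x$odds_ratio, x$p_value, x$pct_row1, x$pct_row2))
  invisible(x)
}
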