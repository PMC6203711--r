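# Statistical primitives used by the somatic filter cascade and the
# downstream cohort analyses. Each returns a `test_result` with a fixed
# orientation so that the cascade's pass/fail rules read directly off the
# p-value. Base R supplies the distributions; the wrappers pin down the
# alternative, the tail and the degenerate-input conventions.

new_test_result <- function(statistic, p_value, alternative, method, df = NA_real_) {
  stopifnot(is.numeric(p_value), length(p_value) == 1L)
  if (is.na(p_value) || p_value < -1e-12 || p_value > 1 + 1e-12) {
    stop("p-value outside [0, 1]: ", p_value)
  }
  structure(
    list(
      statistic = as.numeric(statistic),
      p_value = min(max(as.numeric(p_value), 0), 1),
      alternative = alternative,
      method = method,
      df = as.numeric(df)
    ),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n", sep = "")
  cat(sprintf("statistic = %.6g, p = %.6g, alternative = %s\n",
              x$statistic, x$p_value, x$alternative))
  if (!is.na(x$df)) cat(sprintf("df = %.4g\n", x$df))
  invisible(x)
}

.check_alternative <- function(alternative) {
  match.arg(alternative, c("two_sided", "greater", "less"))
}

.to_base_alt <- function(alternative) {
  c(two_sided = "two.sided", greater = "greater", less = "less")[[alternative]]
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Exact conditional test given fixed margins. The table is
#' \preformatted{   group1  group2
#'   success    a      b
#'   failure    c      d}
#' and `alternative = "greater"` means the odds of success in group 1 exceed
#' those in group 2. The two-sided p-value sums the probabilities of all
#' tables (with the same margins) no more probable than the observed one.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param alternative One of `"two_sided"`, `"greater"`, `"less"`.
#' @return A `test_result`; `statistic` is the conditional odds-ratio
#'   estimate.
#' @examples
#' fisher_exact(10, 0, 0, 10)$p_value  # 2 / choose(20, 10)
#' @export
fisher_exact <- function(a, b, c, d, alternative = "two_sided") {
  alternative <- .check_alternative(alternative)
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("fisher_exact requires non-negative integer counts")
  }
  tab <- matrix(as.integer(counts), nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(tab, alternative = .to_base_alt(alternative))
  new_test_result(unname(ft$estimate), ft$p.value, alternative, "Fisher's exact test")
}

#' Lower-tail exact binomial test against a fixed error rate
#'
#' The sequencing-error screen of the SNV cascade: with `k` alt-supporting
#' reads out of `n` high-quality reads and a putative per-read error rate
#' `f`, the reported p-value is `P(X <= k)` for `X ~ Binomial(n, f)`.
#' A genuine variant carries far more alt reads than errors alone would
#' produce, so it scores near 1 and passes a `p > alpha` rule, while a site
#' with improbably weak support scores low and fails. The orientation is
#' configurable via `tail`.
#'
#' @param k Successes (alt-supporting reads), `0 <= k <= n`.
#' @param n Trials (high-quality depth).
#' @param f Null success rate in (0, 1).
#' @param tail `"lower"` (default, `P(X <= k)`) or `"upper"` (`P(X >= k)`).
#' @return A `test_result` with `statistic = k`.
#' @examples
#' binom_cdf_test(0, 5, 0.1)$p_value  # 0.9^5
#' @export
binom_cdf_test <- function(k, n, f, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  if (!is.finite(k) || !is.finite(n) || k < 0 || n < 0 || k > n) {
    stop("binom_cdf_test requires 0 <= k <= n")
  }
  if (!is.finite(f) || f <= 0 || f >= 1) stop("null rate f must lie in (0, 1)")
  p <- if (tail == "lower") {
    stats::pbinom(k, n, f)
  } else {
    stats::pbinom(k - 1, n, f, lower.tail = FALSE)
  }
  new_test_result(k, p, if (tail == "lower") "less" else "greater",
                  sprintf("Binomial test (f = %g, %s tail)", f, tail))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact distribution when both samples together hold at most `exact_max`
#' observations and there are no ties; otherwise the mid-rank normal
#' approximation with tie correction and continuity correction.
#' `alternative = "less"` tests whether `xs` tends to be lower than `ys`
#' (the cascade uses this with `xs` = alt-read base qualities).
#'
#' @param xs,ys Non-empty numeric vectors.
#' @param alternative One of `"two_sided"`, `"greater"`, `"less"`.
#' @param exact_max Largest combined sample size for which the exact
#'   distribution is used (default 12).
#' @return A `test_result`; `statistic` is the Mann-Whitney U for `xs`.
#' @export
wilcoxon_rank_sum <- function(xs, ys, alternative = "two_sided", exact_max = 12L) {
  alternative <- .check_alternative(alternative)
  if (length(xs) == 0L || length(ys) == 0L) {
    stop("wilcoxon_rank_sum requires non-empty samples")
  }
  ties <- anyDuplicated(c(xs, ys)) > 0L
  use_exact <- !ties && (length(xs) + length(ys)) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(
    xs, ys,
    alternative = .to_base_alt(alternative),
    exact = use_exact, correct = TRUE
  ))
  new_test_result(unname(wt$statistic), wt$p.value, alternative,
                  if (use_exact) "Wilcoxon rank sum test (exact)"
                  else "Wilcoxon rank sum test (normal approximation)")
}

#' Hypergeometric over-representation test
#'
#' Upper-tail p-value `P(X >= k)` for the overlap `k` between a gene set of
#' size `K` and a query list of size `n`, drawn from a universe of size `N`.
#'
#' @param k Observed overlap.
#' @param K Gene-set size within the universe.
#' @param n Query-list size.
#' @param N Universe size.
#' @return A `test_result` with `statistic = k`.
#' @examples
#' hypergeom_overrep(1, 2, 2, 10)$p_value  # 17/45
#' @export
hypergeom_overrep <- function(k, K, n, N) {
  vals <- c(k, K, n, N)
  if (any(!is.finite(vals)) || any(vals < 0)) stop("counts must be non-negative")
  if (K > N || n > N) stop("set and query sizes cannot exceed the universe")
  if (k > min(K, n)) stop("overlap cannot exceed min(set size, query size)")
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  new_test_result(k, p, "greater", "Hypergeometric over-representation test")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the input order, capped at 1.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

.t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2, welch) {
  if (n1 < 2 || n2 < 2) stop("t-test requires n >= 2 per group")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be non-negative")
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) {
      return(list(t = 0, df = n1 + n2 - 2, p = 1))
    }
    stop("degenerate input: zero variance in both groups with unequal means")
  }
  if (welch) {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Two-sample or paired t-test (raw data or summary statistics)
#'
#' Raw-data and summary-statistic entry points compute identically on
#' matching inputs. Welch (unequal-variance) is the default for unpaired
#' comparisons; set `welch = FALSE` for the pooled-variance test. For the
#' summary path supply `mean`, `sd`, `n` per group via `summary1`/`summary2`.
#' Two-sided throughout. When both groups have zero variance and equal
#' means, `p = 1` by convention; zero variance with unequal means is a
#' degenerate-input error.
#'
#' @param x,y Numeric vectors (raw-data path). For `paired = TRUE` they must
#'   align pairwise.
#' @param summary1,summary2 Numeric vectors `c(mean, sd, n)` (summary path);
#'   mutually exclusive with `x`/`y`.
#' @param paired Paired test on `x - y` differences.
#' @param welch Use the Welch-Satterthwaite df (unpaired only).
#' @return A `test_result` with the t statistic and df.
#' @export
t_test <- function(x = NULL, y = NULL, summary1 = NULL, summary2 = NULL,
                   paired = FALSE, welch = TRUE) {
  if (!is.null(summary1) || !is.null(summary2)) {
    if (is.null(summary1) || is.null(summary2)) {
      stop("both summary1 and summary2 are required for the summary path")
    }
    if (paired) stop("the summary-statistic path supports unpaired tests only")
    res <- .t_from_summary(summary1[1], summary1[2], summary1[3],
                           summary2[1], summary2[2], summary2[3], welch)
    return(new_test_result(res$t, res$p, "two_sided",
                           if (welch) "Welch two-sample t-test (summary statistics)"
                           else "Pooled two-sample t-test (summary statistics)",
                           df = res$df))
  }
  if (is.null(x) || is.null(y)) stop("supply x and y, or summary1 and summary2")
  if (paired) {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    if (length(x) < 2) stop("paired t-test requires >= 2 pairs")
    d <- x - y
    if (stats::sd(d) == 0) {
      if (mean(d) == 0) {
        return(new_test_result(0, 1, "two_sided", "Paired t-test",
                               df = length(d) - 1))
      }
      stop("degenerate input: constant nonzero paired differences")
    }
    tt <- stats::t.test(d)
    return(new_test_result(unname(tt$statistic), tt$p.value, "two_sided",
                           "Paired t-test", df = unname(tt$parameter)))
  }
  res <- .t_from_summary(mean(x), stats::sd(x), length(x),
                         mean(y), stats::sd(y), length(y), welch)
  new_test_result(res$t, res$p, "two_sided",
                  if (welch) "Welch two-sample t-test" else "Pooled two-sample t-test",
                  df = res$df)
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param a,b,c,d Cell counts (rows = outcome, columns = cohort).
#' @param continuity Apply the Yates continuity correction.
#' @return A `test_result` with the chi-square statistic on 1 df.
#' @export
chi_square_2x2 <- function(a, b, c, d, continuity = FALSE) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) <= 0) stop("table total must be positive")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate input: zero margin in 2x2 table")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = continuity))
  new_test_result(unname(ct$statistic), ct$p.value, "two_sided",
                  if (continuity) "Chi-square test (Yates corrected)"
                  else "Chi-square test",
                  df = 1)
}
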