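#' Two-sample test of equal proportions
#'
#' Chi-squared test on the 2x2 success/failure table with Yates continuity
#' correction (df = 1, two-sided), as used to compare taxon relative
#' abundances between treatments.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return data.frame row: `test_used`, `statistic`, `p_value`, `n1`, `n2`.
#' @export
equal_proportions_test <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  res <- stats::prop.test(c(x1, x2), c(n1, n2), correct = TRUE)
  data.frame(test_used = "equal_proportions",
             statistic = unname(res$statistic),
             p_value = res$p.value, n1 = n1, n2 = n2,
             stringsAsFactors = FALSE)
}

#' Normality-routed two-sample comparison
#'
#' Shapiro-Wilk is run on each sample; if both retain normality at
#' `alpha_normality` the comparison is Welch's t-test, otherwise a Wilcoxon
#' rank-sum test (exact when both groups have n < 10 and no ties; otherwise
#' the normal approximation with continuity and tie corrections). Both
#' two-sided. A constant sample (Shapiro-Wilk undefined) routes to Wilcoxon.
#'
#' @param a,b Numeric samples (each n >= 3).
#' @param alpha_normality Normality screen level (default 0.05).
#' @return data.frame row: `test_used` (welch_t or wilcoxon), `statistic`,
#'   `p_value`, `n1`, `n2`, `shapiro_p_a`, `shapiro_p_b`.
#' @export
two_sample_auto <- function(a, b, alpha_normality = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) {
    stop("each sample needs at least 3 observations")
  }
  sw <- function(x) {
    if (length(unique(x)) < 2 || length(x) > 5000) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  pa <- sw(a); pb <- sw(b)
  normal <- !is.na(pa) && !is.na(pb) && pa >= alpha_normality && pb >= alpha_normality
  if (normal) {
    res <- stats::t.test(a, b, var.equal = FALSE)
    used <- "welch_t"
  } else {
    used <- "wilcoxon"
    if (length(unique(c(a, b))) == 1L) {
      # every observation tied: no evidence of any difference
      res <- list(statistic = c(W = length(a) * length(b) / 2), p.value = 1)
    } else {
      exact <- length(a) < 10 && length(b) < 10 && !anyDuplicated(c(a, b))
      res <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                                 correct = TRUE))
    }
  }
  data.frame(test_used = used, statistic = unname(res$statistic),
             p_value = res$p.value, n1 = length(a), n2 = length(b),
             shapiro_p_a = pa, shapiro_p_b = pb, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; order-preserving with the input, monotone, capped
#' at 1.
#'
#' @param p Numeric vector of p values.
#' @return Adjusted p values in input order.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Run a family of group comparisons with BH correction
#'
#' Applies [two_sample_auto()] to each named pair of samples and adjusts the
#' resulting p values as one BH family.
#'
#' @param comparisons Named list; each element a list of two numeric samples.
#' @param alpha_normality Passed through.
#' @return data.frame, one row per comparison, with `p_adjusted`.
#' @export
comparison_family <- function(comparisons, alpha_normality = 0.05) {
  rows <- lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    cbind(comparison = nm,
          two_sample_auto(cmp[[1]], cmp[[2]], alpha_normality))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}
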