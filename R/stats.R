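#' Compare two experimental conditions with a two-sample t test
#'
#' Two-sided two-sample t test between two groups of per-cantilever
#' measurements, reported as mean +/- s.e.m. per group with the usual
#' significance stars (* p < 0.05, ** p < 0.01, *** p < 0.001). Welch's
#' unequal-variance variant is the default (group sizes in these assays are
#' rarely balanced); `variant = "student"` gives the classical
#' pooled-variance test.
#'
#' Degenerate inputs are handled by convention rather than error: if both
#' groups have zero variance the test statistic is undefined, and the result
#' is flagged with p = 1 for equal means or p = 0 (|t| = Inf) for different
#' means.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param variant `"welch"` (default) or `"student"`.
#' @return An object of class `comparison_result`: `mean_a`, `mean_b`,
#'   `sem_a`, `sem_b`, `t_statistic`, `p_value`, `df`, `n_a`, `n_b`,
#'   `stars`, `variant`, `degenerate`.
#' @examples
#' compare_conditions(c(1, 2, 3, 4), c(3, 4, 5, 6), variant = "student")
#' @export
compare_conditions <- function(values_a, values_b,
                               variant = c("welch", "student")) {
  variant <- match.arg(variant)
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  res <- list(mean_a = mean(values_a), mean_b = mean(values_b),
              sem_a = sem(values_a), sem_b = sem(values_b),
              n_a = length(values_a), n_b = length(values_b),
              variant = variant, degenerate = FALSE)
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    res$degenerate <- TRUE
    if (res$mean_a == res$mean_b) {
      res$t_statistic <- 0; res$p_value <- 1
    } else {
      res$t_statistic <- sign(res$mean_a - res$mean_b) * Inf
      res$p_value <- 0
    }
    res$df <- NA_real_
  } else {
    tt <- stats::t.test(values_a, values_b,
                        var.equal = (variant == "student"))
    res$t_statistic <- unname(tt$statistic)
    res$p_value <- tt$p.value
    res$df <- unname(tt$parameter)
  }
  res$stars <- significance_stars(res$p_value)
  structure(res, class = "comparison_result")
}

#' Significance stars for a p value
#'
#' Step function with breakpoints exactly at the conventional thresholds:
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `"ns"`
#' otherwise.
#'
#' @param p p value(s) in `[0, 1]`.
#' @return Character vector of annotations.
#' @export
significance_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "comparison (%s t): %.4g +/- %.3g (n=%d) vs %.4g +/- %.3g (n=%d)\n",
    x$variant, x$mean_a, x$sem_a, x$n_a, x$mean_b, x$sem_b, x$n_b))
  cat(sprintf("  t = %.4g, p = %.4g %s%s\n", x$t_statistic, x$p_value,
              x$stars, if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}
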