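#' Group summary triple
#'
#' @param n Sample size (>= 2).
#' @param mean Sample mean, in the measure's units.
#' @param sd Sample standard deviation (> 0).
#' @return A `group_summary` list.
#' @export
group_summary <- function(n, mean, sd) {
  stopifnot(is.numeric(n), n >= 2, is.finite(mean), is.numeric(sd), sd > 0)
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

#' Summarize a raw sample into a group summary
#' @param x Numeric vector, length >= 2.
#' @return A [group_summary()].
#' @export
summarize_group <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2)
  group_summary(length(x), mean(x), stats::sd(x))
}

new_comparison <- function(statistic, df, p, ci, method, estimate) {
  structure(
    list(statistic = statistic, df = df, p_two_sided = p,
         p_sidak = NA_real_, family_size = NA_integer_,
         ci_low = ci[1], ci_high = ci[2], estimate = estimate,
         method = method),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s two-group comparison\n", x$method))
  cat(sprintf("  statistic = %.4g, df = %.4g, two-sided p = %.4g\n",
              x$statistic, x$df, x$p_two_sided))
  if (!is.na(x$ci_low))
    cat(sprintf("  95%% CI of difference: [%.4g, %.4g]\n",
                x$ci_low, x$ci_high))
  if (!is.na(x$p_sidak))
    cat(sprintf("  Sidak-adjusted p = %.4g (family of %d)\n",
                x$p_sidak, x$family_size))
  invisible(x)
}

#' Two-sample t-test from summary statistics
#'
#' Computes Student's (pooled-variance) or Welch's t-test directly from
#' `(n, mean, sd)` triples, as needed when only published summary rows are
#' available. Student uses `df = n1 + n2 - 2`; Welch uses the
#' Welch-Satterthwaite df. The 95% confidence interval of the mean
#' difference (group 1 minus group 2) uses the method's df.
#'
#' @param g1,g2 [group_summary()] objects (or lists with `n`, `mean`, `sd`).
#' @param method `"welch"` (default) or `"student"`.
#' @param conf_level Confidence level for the interval.
#' @return A `comparison_result` (Sidak fields unset; see [family_adjust()]).
#' @examples
#' t_from_summary(group_summary(39, 166.7, 54.74),
#'                group_summary(33, 113.03, 42.96), method = "student")
#' @export
t_from_summary <- function(g1, g2, method = c("welch", "student"),
                           conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(g1$n >= 2, g2$n >= 2, g1$sd > 0, g2$sd > 0)
  diff <- g1$mean - g2$mean
  v1 <- g1$sd^2 / g1$n
  v2 <- g2$sd^2 / g2$n
  if (method == "student") {
    df <- g1$n + g2$n - 2
    sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
    se <- sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  } else {
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  }
  t <- diff / se
  p <- 2 * stats::pt(-abs(t), df)
  crit <- stats::qt(1 - (1 - conf_level) / 2, df)
  new_comparison(t, df, p, diff + c(-1, 1) * crit * se, method, diff)
}

#' Mann-Whitney U test on raw samples
#'
#' Rank-based two-sample comparison: the exact U distribution is used for
#' small samples (combined n of 20 or fewer, no ties) and the normal
#' approximation with tie correction and continuity correction otherwise.
#' Computation is delegated to [stats::wilcox.test()].
#'
#' @param x,y Non-empty numeric vectors.
#' @return A `comparison_result` with `statistic` = U (for `x`), `df = NA`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                           conf.int = FALSE)
  new_comparison(unname(wt$statistic), NA_real_, wt$p.value,
                 c(NA_real_, NA_real_), "mann_whitney",
                 stats::median(x) - stats::median(y))
}

#' Apply the Sidak correction within comparison families
#'
#' Each comparison belongs to an assessment domain (questionnaires, sensory
#' detection, pain thresholds, tolerance, ...); the family size is the number
#' of comparisons sharing the label, and each row's p-value is adjusted as
#' `1 - (1 - p)^family_size`. Family membership is configuration, not
#' inference.
#'
#' @param comparisons Data frame with at least columns `p` and `family`
#'   (character, no NA). Rows with `family = NA` raise an error.
#' @return The data frame with `family_size` and `p_sidak` columns filled.
#' @export
family_adjust <- function(comparisons) {
  stopifnot(is.data.frame(comparisons),
            all(c("p", "family") %in% names(comparisons)))
  if (anyNA(comparisons$family)) {
    stop("every comparison row must carry a family label", call. = FALSE)
  }
  sizes <- table(comparisons$family)
  comparisons$family_size <- as.integer(sizes[comparisons$family])
  comparisons$p_sidak <- sidak_adjust(comparisons$p,
                                      comparisons$family_size)
  comparisons
}

#' Display rounding for p-values
#'
#' Formats p-values the way mixed published tables print them: five decimal
#' places below 0.001, otherwise two significant figures. Raw values should
#' always be retained alongside.
#'
#' @param p Numeric p-value(s).
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 0.001, sprintf("%.5f", p), as.character(signif(p, 2)))
}
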