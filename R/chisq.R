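#' Expected number of rare-allele carriers in a cohort
#'
#' Multiplies the cohort size by a reference carrier frequency. The result is
#' returned unrounded; one-decimal rounding (as printed in cohort summaries,
#' e.g. an expectation of 1.1 carriers among 158 individuals at a carrier
#' frequency of 0.0072) is left to the caller.
#'
#' @param n Cohort size (non-negative).
#' @param carrier_freq Reference carrier frequency in `[0, 1]`.
#' @return Expected carrier count (non-negative real, unrounded).
#' @examples
#' expected_carrier_count(158, 0.0072) # 1.1376, displays as 1.1
#' @export
expected_carrier_count <- function(n, carrier_freq) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  if (!is.numeric(carrier_freq) || carrier_freq < 0 || carrier_freq > 1) {
    stop("`carrier_freq` must lie in [0, 1]", call. = FALSE)
  }
  n * carrier_freq
}

new_chisq_result <- function(chi2, p, layout, expected) {
  structure(
    list(chi2 = chi2, df = 1L, p_two_tail = p, layout = layout,
         expected_counts = expected),
    class = "chisq_result"
  )
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Yates-corrected chi-square (%s)\n", x$layout))
  cat(sprintf("  chi2 = %.4g, df = 1, two-tailed p = %.4g\n",
              x$chi2, x$p_two_tail))
  invisible(x)
}

#' Yates-corrected chi-square goodness-of-fit test on two categories
#'
#' Compares an observed (rare, common) count pair against expected counts,
#' applying the continuity correction `(|O - E| - 0.5)^2 / E` with the
#' corrected deviation floored at zero when `|O - E| < 0.5`. This is the
#' one-sample layout used when a cohort is tested directly against a
#' reference frequency without a reference cohort size.
#'
#' @param observed Numeric pair of observed counts.
#' @param expected Numeric pair of positive expected counts summing (within
#'   `tol`) to the observed total.
#' @param tol Relative tolerance for the total-count consistency check.
#' @return A `chisq_result` with the statistic, df = 1 and two-tailed p-value.
#' @examples
#' yates_chisq_gof(c(4, 154), c(1.1376, 156.8624))
#' @export
yates_chisq_gof <- function(observed, expected, tol = 1e-6) {
  stopifnot(length(observed) == 2L, length(expected) == 2L,
            all(observed >= 0))
  if (any(expected <= 0)) {
    stop("degenerate input: all expected counts must be positive",
         call. = FALSE)
  }
  if (abs(sum(observed) - sum(expected)) >
      tol * max(1, sum(expected))) {
    stop("observed and expected totals disagree", call. = FALSE)
  }
  dev <- pmax(abs(observed - expected) - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  new_chisq_result(chi2, stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                   "goodness_of_fit", as.numeric(expected))
}

#' Yates-corrected chi-square test on a 2x2 contingency table
#'
#' Two-sample layout comparing cohort carrier (or allele) counts against a
#' reference cohort, using the closed form
#' `N (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))` with the corrected
#' cross-product deviation floored at zero.
#'
#' @param table 2x2 matrix of non-negative counts; rows are cohorts,
#'   columns are (rare, common).
#' @return A `chisq_result` with `layout = "contingency_2x2"`.
#' @examples
#' yates_chisq_2x2(rbind(c(4, 154), c(136, 18742)))
#' @export
yates_chisq_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  n <- a + b + c + d
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg <= 0)) {
    stop("degenerate input: every row and column total must be positive",
         call. = FALSE)
  }
  num <- max(abs(a * d - b * c) - n / 2, 0)
  chi2 <- n * num^2 / prod(marg)
  expected <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  new_chisq_result(chi2, stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                   "contingency_2x2", as.numeric(expected))
}

#' Combine discovery and replication cohorts and test carrier enrichment
#'
#' Pools carrier counts and cohort sizes across the discovery and replication
#' cohorts and tests the pooled carrier count against a reference carrier
#' frequency. When the reference cohort size is known the test is a 2x2
#' Yates-corrected contingency test against reference carrier counts
#' (`round(ref_carrier_freq * ref_cohort_size)` by default; set
#' `round_reference = FALSE` for the unrounded variant). Without a reference
#' cohort size the test falls back to the goodness-of-fit layout against
#' expected counts, with a note.
#'
#' @param discovery,replication Length-2 vectors `c(carriers, n)`.
#' @param ref_carrier_freq Reference carrier frequency in `[0, 1]`.
#' @param ref_cohort_size Reference cohort size (individuals), or `NULL`.
#' @param round_reference Round reference carrier counts to whole individuals?
#' @return List with `carriers`, `n`, `expected` (expected carriers in the
#'   pooled cohort) and `chisq` (a `chisq_result`).
#' @examples
#' combine_cohorts(c(3, 100), c(1, 58), 0.0072, 18878)
#' @export
combine_cohorts <- function(discovery, replication, ref_carrier_freq,
                            ref_cohort_size = NULL, round_reference = TRUE) {
  stopifnot(length(discovery) == 2L, length(replication) == 2L,
            discovery[2] > 0, replication[2] > 0,
            discovery[1] <= discovery[2], replication[1] <= replication[2])
  carriers <- discovery[1] + replication[1]
  n <- discovery[2] + replication[2]
  expected <- expected_carrier_count(n, ref_carrier_freq)
  if (is.null(ref_cohort_size) || is.na(ref_cohort_size)) {
    message("no reference cohort size; using goodness-of-fit layout")
    chisq <- yates_chisq_gof(c(carriers, n - carriers),
                             c(expected, n - expected))
  } else {
    ref_carriers <- ref_carrier_freq * ref_cohort_size
    if (round_reference) ref_carriers <- round(ref_carriers)
    chisq <- yates_chisq_2x2(rbind(
      c(carriers, n - carriers),
      c(ref_carriers, ref_cohort_size - ref_carriers)
    ))
  }
  list(carriers = carriers, n = n, expected = expected, chisq = chisq)
}
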