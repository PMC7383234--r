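#' Bonferroni adjustment
#'
#' Multiplies each p-value by the number of tests and caps at 1, preserving
#' input order. Thin wrapper over [stats::p.adjust()] kept as a named step of
#' the enrichment pipeline.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bonferroni_adjust <- function(p) {
  check_pvalues(p)
  if (length(p) == 0L) return(numeric(0))
  stats::p.adjust(p, method = "bonferroni")
}

#' Benjamini-Hochberg step-up q-values
#'
#' Step-up false-discovery-rate adjustment: for sorted p-values,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and returned in input
#' order. Uses [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @examples
#' bh_fdr(c(0.001, 0.01, 0.02, 0.8))
#' @export
bh_fdr <- function(p) {
  check_pvalues(p)
  if (length(p) == 0L) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Sidak family-wise correction
#'
#' `1 - (1 - p)^m` for a family of `m` comparisons. Vectorized over `p`.
#'
#' @param p P-value(s) in `[0, 1]`.
#' @param family_size Number of comparisons in the family (>= 1).
#' @return Adjusted p-value(s).
#' @examples
#' sidak_adjust(0.018, 6) # 0.103
#' @export
sidak_adjust <- function(p, family_size) {
  check_pvalues(p)
  stopifnot(is.numeric(family_size), family_size >= 1)
  1 - (1 - p)^family_size
}

check_pvalues <- function(p) {
  if (length(p) && (!is.numeric(p) || any(is.na(p)) ||
                    any(p < 0) || any(p > 1))) {
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  }
  invisible(p)
}
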