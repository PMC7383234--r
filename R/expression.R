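#' Positive-expression call from a quantification cycle
#'
#' A well is called positive when a Cq value is present and strictly less
#' than the threshold (default 35 cycles); the no-amplification sentinel
#' (`NA`) is negative. Vectorized.
#'
#' @param cq Numeric Cq value(s); `NA` for no amplification.
#' @param threshold Calling threshold, cycles (> 0).
#' @return Logical vector.
#' @examples
#' call_positive(c(27.2, 35, NA)) # TRUE FALSE FALSE
#' @export
call_positive <- function(cq, threshold = 35) {
  stopifnot(threshold > 0)
  !is.na(cq) & cq < threshold
}

#' Per-cell QC from the housekeeping gene
#'
#' A cell passes QC iff its housekeeping gene (internal positive control,
#' e.g. Gapdh) calls positive. Bath-control columns must call negative for
#' every gene; any positive bath well raises a run-level contamination flag.
#'
#' @param m A `cq_matrix` (see [gen_cq_matrix()]) or a list with `cq`
#'   (genes x cells matrix), `housekeeping`, optional `is_bath` and
#'   `threshold`.
#' @param threshold Calling threshold; defaults to the matrix's own.
#' @return List with `pass` (logical per cell; `FALSE` for bath columns),
#'   and `contaminated` (single logical run flag).
#' @export
qc_cells <- function(m, threshold = NULL) {
  stopifnot(is.matrix(m$cq), !is.null(rownames(m$cq)))
  threshold <- threshold %||% m$threshold %||% 35
  if (!m$housekeeping %in% rownames(m$cq)) {
    stop("housekeeping gene '", m$housekeeping, "' not in matrix",
         call. = FALSE)
  }
  is_bath <- m$is_bath %||% rep(FALSE, ncol(m$cq))
  pass <- call_positive(m$cq[m$housekeeping, ], threshold) & !is_bath
  contaminated <- any(call_positive(m$cq[, is_bath, drop = FALSE],
                                    threshold))
  if (contaminated) {
    warning("bath control well(s) amplified: run flagged as contaminated",
            call. = FALSE)
  }
  list(pass = unname(pass), contaminated = contaminated)
}

#' Boolean call matrix from a Cq matrix
#'
#' Applies [call_positive()] elementwise and masks out cells failing QC
#' (calls are only defined for QC-passing cells).
#'
#' @inheritParams qc_cells
#' @return List with `calls` (genes x QC-passing cells logical matrix),
#'   `population` (for those cells) and `qc` (the [qc_cells()] result).
#' @export
call_matrix <- function(m, threshold = NULL) {
  threshold <- threshold %||% m$threshold %||% 35
  qc <- qc_cells(m, threshold)
  keep <- qc$pass
  list(calls = call_positive(m$cq[, keep, drop = FALSE], threshold),
       population = m$population[keep], qc = qc)
}

#' Co-expression summary for an anchor gene and its partners
#'
#' For each population: the percentage (and count) of QC-passing cells
#' positive for the anchor gene, and — among anchor-positive cells — the
#' percentage positive for each partner gene. Percentages are
#' `round(100 * count / denominator)` to the nearest integer; zero
#' denominators yield `NA` percentages (undefined, not 0).
#'
#' @param cm A [call_matrix()] result (or list with `calls`, `population`).
#' @param anchor Anchor gene name.
#' @param partners Character vector of partner gene names.
#' @param populations Populations to summarize; defaults to all present.
#' @return Long-format data frame: `population`, `gene`, `denominator`,
#'   `count`, `percent`.
#' @export
coexpression_summary <- function(cm, anchor, partners,
                                 populations = NULL) {
  calls <- cm$calls
  stopifnot(anchor %in% rownames(calls),
            all(partners %in% rownames(calls)))
  populations <- populations %||% unique(cm$population)
  out <- list()
  for (pop in populations) {
    in_pop <- cm$population == pop
    n_pop <- sum(in_pop)
    anchor_pos <- in_pop & calls[anchor, ]
    n_anchor <- sum(anchor_pos)
    out[[length(out) + 1]] <- data.frame(
      population = pop, gene = anchor, denominator = n_pop,
      count = n_anchor,
      percent = if (n_pop > 0) round(100 * n_anchor / n_pop) else NA_real_,
      stringsAsFactors = FALSE)
    for (g in partners) {
      cnt <- sum(anchor_pos & calls[g, ])
      out[[length(out) + 1]] <- data.frame(
        population = pop, gene = g, denominator = n_anchor, count = cnt,
        percent = if (n_anchor > 0) round(100 * cnt / n_anchor)
                  else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Mean Cq of positive wells per gene
#'
#' Average quantification cycle across QC-passing, positive wells — the
#' quantity behind statements like "mean CT 27.2 for Kcng4 vs 16.3 for
#' Kcnb1" (higher Cq = lower abundance).
#'
#' @param m A `cq_matrix`.
#' @param genes Genes to summarize; defaults to all non-housekeeping rows.
#' @return Named numeric vector of mean Cq values.
#' @export
mean_positive_cq <- function(m, genes = NULL) {
  qc <- qc_cells(m)
  genes <- genes %||% setdiff(rownames(m$cq), m$housekeeping)
  vapply(genes, function(g) {
    v <- m$cq[g, qc$pass]
    v <- v[call_positive(v, m$threshold %||% 35)]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
}
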