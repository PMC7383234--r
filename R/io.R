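#' Read a SNP record table from TSV
#'
#' Tab-separated, UTF-8, header required; `.` denotes a missing field (kept
#' as `NA`, never coerced to zero). Columns follow the contract of
#' [validate_snp_records()].
#'
#' @param path File path.
#' @return Validated SNP record data frame.
#' @export
read_snp_table <- function(path) {
  df <- utils::read.delim(path, na.strings = ".", stringsAsFactors = FALSE,
                          check.names = FALSE)
  required <- c("snp_id", "gene", "consequence", "in_gene_set",
                "ortholog_common_flag", "artifact_flag", "n_assessed",
                "rare_allele_count", "carrier_count", "ref_freq",
                "ref_freq_kind")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("'", path, "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$in_gene_set <- as.logical(df$in_gene_set)
  df$ortholog_common_flag <- as.logical(df$ortholog_common_flag)
  validate_snp_records(df)
  df
}

#' Write a table as TSV with `.` for missing values
#'
#' @param df Data frame.
#' @param path File path.
#' @export
write_tsv_dot <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a genes-x-cells Cq matrix from TSV
#'
#' First column `gene`; remaining columns are cells named
#' `<population>_<index>` (bath controls use population `bath`); `NA` or
#' `.` is the no-amplification sentinel.
#'
#' @param path File path.
#' @param housekeeping Housekeeping gene name.
#' @return A `cq_matrix` list as consumed by [qc_cells()].
#' @export
read_cq_matrix <- function(path, housekeeping = "Gapdh") {
  df <- utils::read.delim(path, na.strings = c("NA", "."),
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene") {
    stop("'", path, "': first column must be 'gene'", call. = FALSE)
  }
  cq <- as.matrix(df[, -1, drop = FALSE])
  rownames(cq) <- df$gene
  population <- sub("_[0-9]+$", "", colnames(cq))
  structure(list(cq = cq, population = population,
                 is_bath = population == "bath",
                 housekeeping = housekeeping, threshold = 35),
            class = "cq_matrix")
}

#' Write a Cq matrix as TSV
#' @param m A `cq_matrix`.
#' @param path File path.
#' @export
write_cq_matrix <- function(m, path) {
  idx <- stats::ave(seq_along(m$population), m$population, FUN = seq_along)
  df <- data.frame(gene = rownames(m$cq), m$cq, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[-1] <- paste0(m$population, "_", idx)
  write_tsv_dot(df, path)
}

#' Run the full genetics analysis chain
#'
#' Scan, multiple-testing correction, filter cascade and (optionally) the
#' discovery + replication combined carrier test, with a log of counts at
#' every stage. Deterministic given its inputs.
#'
#' @param records SNP record table (data frame or TSV path).
#' @param alpha Significance threshold for the cascade gate.
#' @param gate `"q"` (BH) or `"bonferroni"`.
#' @param stages Cascade stage order (see [filter_cascade()]).
#' @param combine Optional list with `discovery`, `replication`
#'   (each `c(carriers, n)`), `ref_carrier_freq` and `ref_cohort_size`
#'   for the combined carrier test.
#' @param ... Passed to [snp_scan()].
#' @return List with `results`, `cascade` (survivors + report), `combined`
#'   (or `NULL`) and `log` (character vector of stage counts).
#' @export
run_genetics_pipeline <- function(records, alpha = 0.05,
                                  gate = c("q", "bonferroni"),
                                  stages = cascade_stages,
                                  combine = NULL, ...) {
  gate <- match.arg(gate)
  if (is.character(records)) records <- read_snp_table(records)
  log <- character(0)
  if (nrow(records) == 0) {
    warning("empty SNP table: nothing to scan", call. = FALSE)
    return(list(results = NULL, cascade = NULL, combined = NULL,
                log = "empty SNP table"))
  }
  results <- snp_scan(records, ...)
  log <- c(log, sprintf("scanned %d SNPs (%d skipped)", nrow(results),
                        length(attr(results, "skipped"))))
  cascade <- filter_cascade(results, records, stages = stages,
                            alpha = alpha, gate = gate)
  for (i in seq_len(nrow(cascade$report))) {
    r <- cascade$report[i, ]
    log <- c(log, sprintf("stage %-16s: %d -> %d", r$stage, r$n_in, r$n_out))
  }
  combined <- NULL
  if (!is.null(combine)) {
    combined <- combine_cohorts(combine$discovery, combine$replication,
                                combine$ref_carrier_freq,
                                combine$ref_cohort_size)
    log <- c(log, sprintf(
      "combined cohort: %d carriers / %d (expected %.4g), chi2 = %.4g, p = %.4g",
      combined$carriers, combined$n, combined$expected,
      combined$chisq$chi2, combined$chisq$p_two_tail))
  }
  list(results = results, cascade = cascade, combined = combined, log = log)
}

#' Write scan results (with filter traces) as TSV
#'
#' @param results Scan results, optionally carrying a `filter_trace` column.
#' @param path File path.
#' @export
write_scan_results <- function(results, path) {
  write_tsv_dot(results, path)
}
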