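#' @keywords internal
snp_consequences <- c("missense_deleterious", "missense_tolerated",
                      "nonsense", "splice", "start_loss", "inframe_indel",
                      "synonymous", "other")

protein_changing <- c("missense_deleterious", "nonsense", "splice",
                      "start_loss", "inframe_indel")

#' Validate a SNP record table
#'
#' Checks the column contract of the per-SNP cohort table: identifiers,
#' annotation flags, per-SNP coverage (`n_assessed`), rare-allele and carrier
#' counts, and the reference frequency with its kind (`allele` counts rare
#' alleles over `2 * n_assessed` chromosomes; `carrier` counts individuals
#' with at least one rare allele over `n_assessed`).
#'
#' @param records Data frame of SNP records.
#' @return The records, invisibly, after validation.
#' @export
validate_snp_records <- function(records) {
  required <- c("snp_id", "gene", "consequence", "in_gene_set",
                "ortholog_common_flag", "artifact_flag", "n_assessed",
                "rare_allele_count", "carrier_count", "ref_freq",
                "ref_freq_kind")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop("SNP table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(records$snp_id)) {
    stop("duplicated snp_id in SNP table", call. = FALSE)
  }
  bad <- !records$consequence %in% snp_consequences
  if (any(bad)) {
    stop("unknown consequence value(s): ",
         paste(unique(records$consequence[bad]), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(records$n_assessed >= 0),
            all(records$carrier_count <= records$n_assessed),
            all(records$rare_allele_count <= 2 * records$n_assessed),
            all(records$rare_allele_count >= records$carrier_count),
            all(records$ref_freq_kind %in% c("allele", "carrier")),
            all(is.na(records$ref_freq) |
                  (records$ref_freq >= 0 & records$ref_freq <= 1)))
  invisible(records)
}

#' Per-SNP cohort-vs-reference enrichment scan
#'
#' For every SNP, builds observed rare-versus-common counts (rare allele
#' counts over `2 * n_assessed` trials when `ref_freq_kind = "allele"`,
#' carrier counts over `n_assessed` trials when `"carrier"`), tests the
#' deviation from the reference frequency with a two-tailed Yates-corrected
#' chi-square (2x2 contingency layout against reference cohort counts when
#' `ref_cohort_size` is available, goodness-of-fit otherwise), and attaches
#' Bonferroni and Benjamini-Hochberg corrections computed over the set of
#' SNPs actually tested in the run.
#'
#' Records with a missing reference frequency, or coverage below
#' `min_coverage`, are skipped with a warning and recorded in the
#' `skipped` attribute. SNPs whose expected rare count falls below
#' `min_expected` are still tested but flagged `small_expected` (the original
#' analysis itself tested an expectation of 0.7).
#'
#' @param records SNP record table (see [validate_snp_records()]).
#' @param min_coverage Minimum `n_assessed` for a SNP to be tested.
#' @param min_expected Expected-count floor below which results are flagged.
#' @param layout `"auto"` (2x2 when `ref_cohort_size` present, else
#'   goodness-of-fit), `"gof"`, or `"2x2"` (errors if sizes are missing).
#' @param round_reference Round reference counts to whole units in the 2x2
#'   layout.
#' @return Data frame of per-SNP results ordered as the input, with columns
#'   `snp_id`, `observed`, `expected`, `trials`, `layout`, `chi2`, `p`,
#'   `p_bonferroni`, `q_bh`, `small_expected`. Skipped SNP ids are in
#'   `attr(, "skipped")`.
#' @export
snp_scan <- function(records, min_coverage = 1, min_expected = 0.5,
                     layout = c("auto", "gof", "2x2"),
                     round_reference = TRUE) {
  layout <- match.arg(layout)
  validate_snp_records(records)

  skip <- is.na(records$ref_freq) | records$n_assessed < min_coverage
  if (any(skip)) {
    warning(sum(skip), " SNP(s) skipped (missing ref_freq or coverage < ",
            min_coverage, ")", call. = FALSE)
  }
  kept <- records[!skip, , drop = FALSE]
  n <- nrow(kept)
  res <- data.frame(
    snp_id = character(n), observed = numeric(n), expected = numeric(n),
    trials = numeric(n), layout = character(n), chi2 = numeric(n),
    p = numeric(n), stringsAsFactors = FALSE
  )
  has_ref_n <- "ref_cohort_size" %in% names(kept)
  for (i in seq_len(n)) {
    r <- kept[i, ]
    if (r$ref_freq_kind == "allele") {
      trials <- 2 * r$n_assessed
      obs <- r$rare_allele_count
      ref_trials <- if (has_ref_n && !is.na(r$ref_cohort_size))
        2 * r$ref_cohort_size else NA_real_
    } else {
      trials <- r$n_assessed
      obs <- r$carrier_count
      ref_trials <- if (has_ref_n && !is.na(r$ref_cohort_size))
        r$ref_cohort_size else NA_real_
    }
    use_2x2 <- switch(layout,
      auto = !is.na(ref_trials),
      gof = FALSE,
      `2x2` = {
        if (is.na(ref_trials))
          stop("layout '2x2' requires ref_cohort_size for every tested SNP",
               call. = FALSE)
        TRUE
      })
    expected <- trials * r$ref_freq
    if (use_2x2) {
      ref_obs <- ref_trials * r$ref_freq
      if (round_reference) ref_obs <- round(ref_obs)
      ct <- yates_chisq_2x2(rbind(c(obs, trials - obs),
                                  c(ref_obs, ref_trials - ref_obs)))
    } else {
      ct <- yates_chisq_gof(c(obs, trials - obs),
                            c(expected, trials - expected))
    }
    res$snp_id[i] <- r$snp_id
    res$observed[i] <- obs
    res$expected[i] <- expected
    res$trials[i] <- trials
    res$layout[i] <- ct$layout
    res$chi2[i] <- ct$chi2
    res$p[i] <- ct$p_two_tail
  }
  res$p_bonferroni <- bonferroni_adjust(res$p)
  res$q_bh <- bh_fdr(res$p)
  res$small_expected <- res$expected < min_expected
  attr(res, "skipped") <- records$snp_id[skip]
  res
}

#' Rank scan results by significance
#'
#' Stable ordering by raw p-value with ties broken by SNP id.
#'
#' @param results Output of [snp_scan()].
#' @return The results, reordered.
#' @export
rank_results <- function(results) {
  results[order(results$p, results$snp_id), , drop = FALSE]
}

cascade_stages <- c("significance", "protein_changing", "gene_set",
                    "ortholog", "artifact")

#' Annotation filter cascade over scan results
#'
#' Applies, in configurable order, the filtering stages of the enrichment
#' analysis: a significance gate (BH q or Bonferroni p below `alpha`), a
#' clear-cut protein-changing consequence filter (deleterious missense,
#' nonsense, splice, start-loss, in-frame indel), a gene-set membership
#' filter (e.g. ion-channel genes), removal of SNPs whose rare allele is
#' common in mammalian orthologs, and removal of flagged calling or
#' alignment artifacts.
#'
#' @param results Output of [snp_scan()].
#' @param records The SNP record table the scan was run on.
#' @param stages Character vector of stage names, applied in order. Any of
#'   `"significance"`, `"protein_changing"`, `"gene_set"`, `"ortholog"`,
#'   `"artifact"`.
#' @param alpha Significance threshold for the gate stage.
#' @param gate `"q"` (BH) or `"bonferroni"` for the significance stage.
#' @return List with `results` (survivors, plus a `filter_trace` column of
#'   semicolon-joined `stage:flag` pairs) and `report`, a data frame with one
#'   row per stage: `stage`, `n_in`, `n_out` and `removed` (comma-joined
#'   SNP ids).
#' @export
filter_cascade <- function(results, records,
                           stages = cascade_stages,
                           alpha = 0.05, gate = c("q", "bonferroni")) {
  gate <- match.arg(gate)
  unknown <- setdiff(stages, cascade_stages)
  if (length(unknown)) {
    stop("unknown cascade stage(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(results$snp_id, records$snp_id)
  if (anyNA(idx)) stop("scan results contain SNPs absent from records",
                       call. = FALSE)
  ann <- records[idx, , drop = FALSE]

  pass_by_stage <- list(
    significance = if (gate == "q") results$q_bh < alpha
                   else results$p_bonferroni < alpha,
    protein_changing = ann$consequence %in% protein_changing,
    gene_set = as.logical(ann$in_gene_set),
    ortholog = !as.logical(ann$ortholog_common_flag),
    artifact = ann$artifact_flag == "none"
  )

  alive <- rep(TRUE, nrow(results))
  report <- data.frame(stage = character(0), n_in = integer(0),
                       n_out = integer(0), removed = character(0),
                       stringsAsFactors = FALSE)
  trace <- rep("", nrow(results))
  for (s in stages) {
    pass <- pass_by_stage[[s]]
    n_in <- sum(alive)
    removed <- results$snp_id[alive & !pass]
    trace <- paste0(trace, ifelse(nchar(trace) > 0, ";", ""),
                    s, ":", ifelse(pass, "pass", "fail"))
    alive <- alive & pass
    report <- rbind(report, data.frame(
      stage = s, n_in = n_in, n_out = sum(alive),
      removed = paste(removed, collapse = ","),
      stringsAsFactors = FALSE))
  }
  out <- results[alive, , drop = FALSE]
  out$filter_trace <- trace[alive]
  list(results = out, report = report)
}
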