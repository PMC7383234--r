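#!/usr/bin/env Rscript
# Simulate the genetic study design: a discovery-sized cohort (n = 100)
# genotyped at 500 SNPs with population reference frequencies and 5%
# coverage dropout, one SNP carrying a genuinely enriched rare allele
# (reference carrier frequency 0.02, enriched x6 in the cohort). SNP
# annotations (consequence class, ion-channel gene-set membership,
# ortholog-conservation and artifact flags) are drawn so the filter
# cascade has realistic attrition; the planted SNP is a deleterious
# missense variant in an ion-channel gene, like the study's hit.

suppressPackageStartupMessages(library(kv64pain))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

spec <- cohort_spec(
  n_individuals = 100, n_snps = 500, freq_range = c(1e-3, 0.3),
  spike = data.frame(index = 42, multiplier = 6, ref_freq = 0.02),
  dropout = 0.05
)
g <- gen_cohort(spec, seed = seed)

records <- with_local_seed(seed + 1L, {
  r <- g$records
  n <- nrow(r)
  r$consequence <- sample(
    c("missense_deleterious", "missense_tolerated", "synonymous",
      "nonsense", "splice", "other"),
    n, replace = TRUE, prob = c(0.25, 0.25, 0.30, 0.05, 0.05, 0.10))
  r$in_gene_set <- runif(n) < 0.10          # ion-channel genes
  r$ortholog_common_flag <- runif(n) < 0.10 # rare allele common in orthologs
  r$artifact_flag <- ifelse(runif(n) < 0.05, "allele_calling_error", "none")
  # the planted SNP is a clean deleterious missense in an ion channel
  r$consequence[42] <- "missense_deleterious"
  r$in_gene_set[42] <- TRUE
  r$ortholog_common_flag[42] <- FALSE
  r$artifact_flag[42] <- "none"
  r
})

write_tsv_dot(records, "results/cohort_snp_table.tsv")
write_tsv_dot(g$truth, "results/cohort_truth.tsv")

spiked <- records[g$truth$spiked, ]
cat(sprintf(
  "Simulated %d SNPs x %d individuals (5%% coverage dropout).\n",
  spec$n_snps, spec$n_individuals))
cat(sprintf(
  "Planted enrichment at %s: %d carriers observed vs %.2f expected at the reference frequency.\n",
  spiked$snp_id, spiked$carrier_count,
  spiked$n_assessed * spiked$ref_freq))
cat("Wrote results/cohort_snp_table.tsv and results/cohort_truth.tsv\n")
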