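# Minimal SNP record constructor for fixtures; defaults pass every
# annotation filter.
make_records <- function(n = 1, snp_id = sprintf("rs%03d", seq_len(n)),
                         gene = sprintf("G%03d", seq_len(n)),
                         consequence = "missense_deleterious",
                         in_gene_set = TRUE, ortholog_common_flag = FALSE,
                         artifact_flag = "none", n_assessed = 100,
                         rare_allele_count = 0, carrier_count = 0,
                         ref_freq = 0.01, ref_freq_kind = "carrier",
                         ref_cohort_size = NA) {
  data.frame(snp_id = snp_id, gene = gene, consequence = consequence,
             in_gene_set = in_gene_set,
             ortholog_common_flag = ortholog_common_flag,
             artifact_flag = artifact_flag, n_assessed = n_assessed,
             rare_allele_count = rare_allele_count,
             carrier_count = carrier_count, ref_freq = ref_freq,
             ref_freq_kind = ref_freq_kind,
             ref_cohort_size = ref_cohort_size,
             stringsAsFactors = FALSE)
}
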