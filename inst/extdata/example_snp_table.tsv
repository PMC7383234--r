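snp_id	gene	consequence	in_gene_set	ortholog_common_flag	artifact_flag	n_assessed	rare_allele_count	carrier_count	ref_freq	ref_freq_kind	ref_cohort_size
rs001	KCNG4	missense_deleterious	TRUE	FALSE	none	100	9	9	0.0072	carrier	18878
rs002	SCN9A	synonymous	TRUE	FALSE	none	98	3	3	0.02	carrier	.
rs003	TTN	missense_deleterious	FALSE	FALSE	none	100	8	8	0.01	carrier	.
rs004	KCNQ2	missense_deleterious	TRUE	TRUE	none	95	7	7	0.012	carrier	.
rs005	TRPV1	missense_deleterious	TRUE	FALSE	homolog_misalignment	97	8	8	0.011	carrier	.
rs006	CACNA1A	missense_tolerated	TRUE	FALSE	none	100	2	2	0.015	carrier	.
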