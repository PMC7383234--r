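Package: kv64pain
Title: Rare-Allele Enrichment, Sensory Phenotyping and Kv Channel
    Electrophysiology Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementation of the statistical analyses behind a
    cohort study linking a rare KCNG4 (Kv6.4) allele to reduced labor pain:
    a cohort-versus-reference SNP allele-frequency enrichment scan with
    Yates-corrected chi-square tests, Bonferroni and Benjamini-Hochberg
    correction and an annotation filter cascade; discovery-plus-replication
    combined carrier testing; two-group quantitative sensory testing
    statistics with Sidak family correction; voltage-clamp curve fitting
    (Boltzmann activation, single and double Boltzmann inactivation,
    exponential recovery, toxin-subtraction current isolation) and
    current-clamp action-potential threshold extraction; and single-cell
    qRT-PCR expression calling with co-expression summaries. Includes
    seeded synthetic-data generators for every input shape so the whole
    pipeline runs and tests without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
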