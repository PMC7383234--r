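#!/usr/bin/env Rscript
# Single-cell qRT-PCR expression calling: generate a Cq matrix for
# thoracolumbar (TL) and lumbosacral (LS) uterine sensory neurons at the
# observed positivity rates, QC on the housekeeping gene, call positives
# below 35 cycles, and summarize co-expression around the Kcng4 anchor.

suppressPackageStartupMessages(library(kv64pain))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

m <- gen_cq_matrix(pops = c(TL = 44, LS = 45), n_bath = 3, seed = seed)
write_cq_matrix(m, "results/cq_matrix.tsv")

cm <- call_matrix(m)
cat(sprintf("QC: %d of %d cells pass (housekeeping positive); contamination: %s\n",
            sum(cm$qc$pass), sum(!m$is_bath),
            if (cm$qc$contaminated) "FLAGGED" else "none"))

s <- coexpression_summary(cm, "Kcng4", c("Kcnb1", "Trpv1", "Scn10a"))
write_tsv_dot(s, "results/coexpression_summary.tsv")
cat("Co-expression around the Kcng4 anchor (percent [count of denominator]):\n")
for (i in seq_len(nrow(s))) {
  cat(sprintf("  %-3s %-7s %3.0f%% [%d of %d]\n", s$population[i],
              s$gene[i], s$percent[i], s$count[i], s$denominator[i]))
}

mu <- mean_positive_cq(m, c("Kcng4", "Kcnb1"))
cat(sprintf("Mean Cq among positives: Kcng4 %.1f vs Kcnb1 %.1f (higher = less abundant)\n",
            mu[["Kcng4"]], mu[["Kcnb1"]]))
cat("Wrote results/cq_matrix.tsv and results/coexpression_summary.tsv\n")
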