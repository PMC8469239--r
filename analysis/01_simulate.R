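#!/usr/bin/env Rscript
# Stage 1: generate the study-scale synthetic cohort.
#
# 40 + 36 tumor samples in two latent transcriptional subtypes, 2,000
# genes of which 40 are informative at log2 fold change 2, a death hazard
# ratio of 6 for the second subtype, 20 benign/normal (NAG) samples near
# subtype 1, and mutation rates for the eight recurrent driver genes.
# Writes expression.tsv / clinical.tsv / mutations.tsv / truth.json under
# results/cohort/.

library(accumap)

spec <- default_paper_like_spec()   # fixed documented seed 20210917
cohort <- simulate_cohort(spec)
paths <- write_cohort(cohort, "results/cohort")

cat("Simulated cohort:\n")
cat("  samples:", ncol(cohort$expression$values),
    "(", sum(cohort$truth$cluster_label == "1"), "subtype 1,",
    sum(cohort$truth$cluster_label == "2"), "subtype 2,",
    sum(cohort$truth$cluster_label == "benign"), "benign )\n")
cat("  genes:", nrow(cohort$expression$values),
    " informative:", length(cohort$truth$informative_gene_ids), "\n")
cat("  events observed:", sum(cohort$clinical$event), "\n")
cat("  written:", paste(basename(unname(paths)), collapse = ", "),
    "-> results/cohort/\n")
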