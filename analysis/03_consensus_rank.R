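#!/usr/bin/env Rscript
# Stage 3: consensus random-forest marker ranking.
#
# 100 forests of 1,000 trees on independent stratified 50/50 splits of the
# raw FPKM matrix, per-model top-100 importance lists aggregated by
# occurrence count and mean rank, 5-fold cross-validation, and the
# direction audit of the consensus genes between the two clusters.

library(accumap)

x <- read_expression("results/cohort/expression.tsv")
clusters <- read.delim("results/clusters.tsv")
truth <- jsonlite::read_json("results/cohort/truth.json")

ass <- structure(clusters, class = c("ClusterAssignment", "data.frame"))
tumor <- ass$sample_id[!is.na(ass$cluster)]
xt <- expression_matrix(x$values[, tumor], x$gene_ids, tumor)

ens <- run_ensemble(xt, ass, n_models = 100, n_trees = 1000, seed = 20210917)
s <- ens$accuracy_summary
cat(sprintf(
  "Ensemble test accuracy: min %.2f%%, max %.2f%%, mean %.2f%% (%d/100 perfect)\n",
  100 * s["min"], 100 * s["max"], 100 * s["mean"], s["n_perfect"]))

cv <- cross_validate(xt, ass, n_folds = 5, n_trees = 1000, seed = 20210917)
cat(sprintf("5-fold CV accuracy: %.2f%% +/- %.2f%%\n",
            100 * cv$mean, 100 * cv$sd))

consensus <- aggregate_consensus(ens, top_k = 100)
planted <- unlist(truth$informative_gene_ids)
cat(sprintf("Planted informative genes recovered in consensus top-100: %d/%d\n",
            sum(planted %in% consensus_genes(consensus)), length(planted)))

audit <- direction_audit(xt, ass, consensus)
cat("Direction of consensus genes:", sum(audit$direction == "up_in_2"),
    "up in cluster 2,", sum(audit$direction == "up_in_1"), "up in cluster 1\n")

write.table(as.data.frame(consensus), "results/consensus.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(as.data.frame(audit), "results/direction_audit.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/consensus.tsv, results/direction_audit.tsv\n")
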