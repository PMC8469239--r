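#!/usr/bin/env Rscript
# Stage 4: survival and mutation statistics on the called clusters.
#
# Kaplan-Meier curves with median survival per cluster, log-rank test,
# univariate Cox hazard ratio, Kruskal-Wallis association of driver-gene
# mutation status with the clusters, and per-gene expression comparisons
# across cluster1 / cluster2 / NAG groups for the top consensus markers.

library(accumap)

x <- read_expression("results/cohort/expression.tsv")
clin <- read_clinical("results/cohort/clinical.tsv")
mut <- read_mutations("results/cohort/mutations.tsv")
clusters <- read.delim("results/clusters.tsv")
consensus <- read.delim("results/consensus.tsv")

ass <- structure(clusters, class = c("ClusterAssignment", "data.frame"))
cl <- clin[match(ass$sample_id, clin$sample_id), ]
ok <- !is.na(ass$cluster)
tm <- cl$os_time[ok]; ev <- cl$event[ok]; gl <- ass$cluster[ok]

for (g in sort(unique(gl))) {
  km <- km_estimate(tm[gl == g], ev[gl == g], group = g)
  cat(sprintf("Cluster %s: n = %d, median OS = %s years\n", g, sum(gl == g),
              format(round(km$median, 2))))
}
lr <- logrank_test(tm, ev, gl)
cox <- cox_univariate(tm, ev, gl)
cat(sprintf("Log-rank chi-square %.2f, p = %.3g\n", lr$statistic, lr$p_value))
cat(sprintf("Cox HR (cluster 2 vs 1) %.2f (95%% CI %.2f-%.2f, p = %.3g)\n",
            cox$hazard_ratio, cox$ci_lower, cox$ci_upper, cox$p_value))

assoc <- mutation_cluster_association(mut, ass)
cat("\nMutation association (Kruskal-Wallis on 0/1 status):\n")
print(assoc[order(assoc$kw_p), c("gene", "mut1", "n1", "mut2", "n2", "kw_p")],
      row.names = FALSE)

# group comparison of the top 10 consensus genes incl. benign samples
grp <- setNames(
  ifelse(clin$sample_id %in% ass$sample_id[ok & ass$cluster == 1], "cluster1",
  ifelse(clin$sample_id %in% ass$sample_id[ok & ass$cluster == 2], "cluster2",
  ifelse(clin$group == "NAG", "NAG", NA))), clin$sample_id)
grp <- grp[!is.na(grp)]
top10 <- head(consensus$gene[!is.na(consensus$final_rank)], 10)
cmp <- group_expression_comparison(x, grp, top10)
cat("\nSignificant pairs among top-10 consensus genes:",
    sum(cmp$tier != "ns", na.rm = TRUE), "of", sum(!cmp$skipped), "\n")

write.table(assoc, "results/mutation_association.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cmp, "results/group_comparison.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/mutation_association.tsv, results/group_comparison.tsv\n")
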