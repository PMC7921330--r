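#!/usr/bin/env Rscript
# Stage 3: build inverse miRNA-mRNA pairs from the DE calls and the
# score-filtered target map, flag lens enrichment at both stages, assign
# priority tiers, and test the inverse correlation of paired fold changes.

library(mirlens)

sim_dir <- "results/sim"
de <- read.delim("results/mirna_de.tsv")
mrna_p4 <- read.delim(file.path(sim_dir, "mrna_de_p4.tsv"))
mrna_p30 <- read.delim(file.path(sim_dir, "mrna_de_p30.tsv"))
targets <- filter_targets(read_target_map(file.path(sim_dir, "target_map.tsv")),
                          min_score = 50)

pairs <- pair_inverse(de, mrna_p4, targets, mrna_p30)
pairs <- enrichment_filter(pairs,
  read_enrichment_table(file.path(sim_dir, "enrichment_p4.tsv")), "p4")
pairs <- enrichment_filter(pairs,
  read_enrichment_table(file.path(sim_dir, "enrichment_p30.tsv")), "p30")
pairs <- assign_tiers(pairs)
write.table(pairs, "results/pairs_tiered.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

corr <- inverse_correlation(pairs, de, mrna_p4)
gs <- attr(pairs, "group_summary")
ts <- attr(pairs, "tier_summary")
for (d in c("up", "down")) {
  cat(sprintf("%s-miRNA group: %d pairs over %d unique mRNAs; tiers top=%d high=%d promising=%d\n",
              d, gs$n_pairs[gs$mirna_direction == d],
              gs$n_unique_mrnas[gs$mirna_direction == d],
              ts$top[ts$mirna_direction == d],
              ts$high[ts$mirna_direction == d],
              ts$promising[ts$mirna_direction == d]))
}
cat(sprintf("inverse correlation of paired log2 fold changes: r = %.3f (p = %.2g, n = %d)\n",
            corr$r, corr$p, corr$n_pairs))
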