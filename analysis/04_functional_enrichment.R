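#!/usr/bin/env Rscript
# Stage 4: hypergeometric gene-set enrichment of the prioritized target
# mRNAs, with functional clustering of similar terms and the -log10
# geometric-mean enrichment score.

library(mirlens)

pairs <- read.delim("results/pairs_tiered.tsv")
annot <- read_gmt("results/sim/annotation.gmt")
query <- unique(pairs$mrna[pairs$tier != "unranked"])

terms <- term_enrichment(query, annot)
clusters <- cluster_terms(terms[terms$p <= 0.05, ], annot)
write.table(terms, "results/go_terms.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(clusters, "results/go_clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("%d/%d terms at p <= 0.05; %d clusters, %d with enrichment score > 1.0\n",
            sum(terms$p <= 0.05), nrow(terms), nrow(clusters),
            sum(clusters$top)))
if (nrow(clusters))
  cat(sprintf("top cluster: %s (score %.2f, %d terms)\n",
              clusters$best_term_name[1], clusters$enrichment_score[1],
              clusters$n_terms[1]))
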