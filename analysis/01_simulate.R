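#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Emulates a knockout-vs-control lens miRNA profiling experiment: a
# 700-feature intensity matrix over 3 + 3 replicates with 14 elevated and 8
# reduced miRNAs planted at 1.2-2.2-fold, two-stage mRNA DE tables in which
# the planted miRNAs' true targets move inversely, a scored target map with
# sub-threshold decoys, per-stage lens-enrichment tables, seven perturbation
# DE datasets with 80% planted direction agreement, a gene-set annotation and
# a qPCR plate. Ground truth is written alongside for the later stages to
# check themselves against.

library(mirlens)

sim_dir <- "results/sim"
design <- synthetic_design(seed = 20260919L)
g <- generate_study(design, sim_dir)

writeLines(sprintf("%s: %s", names(c(
  mirna_matrix = "mirna_matrix.tsv", groups = "groups.tsv",
  mrna_de_p4 = "mrna_de_p4.tsv", mrna_de_p30 = "mrna_de_p30.tsv",
  target_map = "target_map.tsv", enrichment_p4 = "enrichment_p4.tsv",
  enrichment_p30 = "enrichment_p30.tsv", annotation = "annotation.gmt",
  perturbation_manifest = "perturbation_manifest.tsv", qpcr = "qpcr_ct.tsv")),
  c("mirna_matrix.tsv", "groups.tsv", "mrna_de_p4.tsv", "mrna_de_p30.tsv",
    "target_map.tsv", "enrichment_p4.tsv", "enrichment_p30.tsv",
    "annotation.gmt", "perturbation_manifest.tsv", "qpcr_ct.tsv")),
  file.path(sim_dir, "run.cfg"))

tr <- g$truth
cat(sprintf("wrote %s: %d planted DE miRNAs (%d up, %d down), %d true pairs over %d unique target mRNAs\n",
            sim_dir, nrow(tr$mirnas), sum(tr$mirnas$direction == "up"),
            sum(tr$mirnas$direction == "down"), nrow(tr$pairs),
            length(unique(tr$pairs$mrna))))
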