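#!/usr/bin/env Rscript
# Stage 5: derive the signed regulatory module downstream of the perturbed
# regulator, export it as SIF and GraphML, and quantify direction
# concordance of the network targets across the seven perturbation DE
# datasets (gain-of-function datasets compared with inverted expectation).

library(mirlens)

sim_dir <- "results/sim"
de <- read.delim("results/mirna_de.tsv")
pairs <- read.delim("results/pairs_tiered.tsv")

edges <- build_module(de, pairs)
export_graph(edges, "results/network.sif", "sif")
export_graph(edges, "results/network.graphml", "graphml")

man <- read.delim(file.path(sim_dir, "perturbation_manifest.tsv"))
tables <- setNames(lapply(file.path(sim_dir, man$path), read.delim),
                   man$dataset_id)
mrna_p4 <- read.delim(file.path(sim_dir, "mrna_de_p4.tsv"))
refd <- setNames(mrna_p4$direction, mrna_p4$feature)
targets <- unique(pairs$mrna)
rep <- concordance(targets, tables, refd[targets],
                   setNames(man$perturbation_kind, man$dataset_id))
write.table(rep$per_target, "results/concordance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- read.delim(file.path(sim_dir, "truth_concordance.tsv"))
cat(sprintf("network: %d edges (%d regulator->miRNA, %d miRNA->mRNA)\n",
            nrow(edges), sum(edges$source == "Tdrd7"),
            sum(edges$source != "Tdrd7")))
cat(sprintf("%d/%d targets misexpressed in >= 1 perturbation dataset (%.0f%%)\n",
            rep$n_misexpressed, rep$n_present, 100 * rep$frac_misexpressed))
cat(sprintf("%.1f%% of misexpressed targets concordant (planted: %.0f%%)\n",
            100 * rep$frac_concordant, 100 * mean(truth$concordant)))
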