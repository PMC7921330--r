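#!/usr/bin/env Rscript
# Stage 6: qPCR confirmation statistics. Relative expression per assay by
# 2^-ddCt against the reference panel (miR-17, Gapdh, Actb) and a
# group-effect p-value from the two-level nested ANOVA (technical replicates
# nested in biological replicates).

library(mirlens)

ct <- read_qpcr_table("results/sim/qpcr_ct.tsv")
refs <- intersect(c("miR-17", "Gapdh", "Actb"), unique(ct$assay))
assays <- setdiff(unique(ct$assay), refs)
panel <- qpcr_panel(ct, assays, refs)
write.table(panel, "results/qpcr_results.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- read.delim("results/sim/truth_qpcr.tsv")
planted <- setNames(truth$ddct, truth$assay)
for (i in seq_len(nrow(panel)))
  cat(sprintf("%s: 2^-ddCt = %.2f (planted %.2f), %s in knockout, nested-ANOVA p = %.3g\n",
              panel$assay[i], panel$rel_expr[i],
              2^(-planted[[panel$assay[i]]]), panel$direction[i], panel$p[i]))
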