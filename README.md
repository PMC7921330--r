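# mirlens

Integrative miRNA–mRNA analysis for lens transcriptomics: differential
microRNA calling from intensity microarrays, inverse miRNA–mRNA target
pairing, tiered candidate prioritization with lens-enrichment evidence,
gene-set enrichment with functional clustering, signed regulatory-network
derivation with cross-perturbation concordance, and 2^−ΔΔCt qPCR statistics
with a two-level nested ANOVA.

## The problem

A regulator of post-transcriptional control (here the Tudor-domain protein
Tdrd7, whose loss causes juvenile cataract) is knocked out; lens miRNAs are
profiled on intensity microarrays in knockout vs. control, and the question
is which miRNAs move, which of their predicted target mRNAs move *the other
way*, which of those inverse pairs matter for the tissue, and whether the
derived regulatory network is consistent with independent perturbations of
other lens regulators. The package implements each step as a tested,
reusable function and ships a synthetic-data generator that plants all of
the structure (differential miRNAs, true targets, enrichment, concordance),
so the whole pipeline is exercised end to end without any external download.

## The statistics at the core

* **Signed fold change.** Group-mean ratios on the signed convention
  `FC = m_case/m_ctrl` if `m_case ≥ m_ctrl`, else `−m_ctrl/m_case`, so
  `|FC| ≥ 1` always and a 2-fold suppression prints as −2.0.
* **Differential calling.** Quantile normalization across arrays, then a
  two-sample t-test on log2 intensities per feature (pooled variance by
  default — exactly calibrated at 3 + 3 replicates — with Welch and a
  variance-shrinkage weight as options). A feature is called at
  `|FC| ≥ 1.2` and `p ≤ 0.05`; BH q-values are reported alongside.
* **Inverse pairing and tiers.** Predicted targets at score ≥ 50 are kept;
  pairs where the miRNA and its target mRNA move oppositely are retained and
  tiered top/high/promising by differential expression at two stages and
  lens enrichment (expression ≥ 100, enrichment FC > 1) at two stages, with
  a configurable first-match-wins rule grammar.
* **Inverse correlation.** Pearson r between paired signed log2 fold
  changes, two-sided p from the t transform.
* **Enrichment.** Upper-tail hypergeometric p per gene-set term with BH
  adjustment; similar terms are merged by Jaccard single linkage and scored
  by −log10 of the geometric mean of member p-values (score > 1.0 flags top
  clusters).
* **Network concordance.** Wild-type-frame signed edges
  (regulator→miRNA→mRNA); per network target, the fraction misexpressed in
  independent perturbation datasets and the fraction with ≥ 1
  same-direction call (gain-of-function datasets compared with inverted
  expectation).
* **qPCR.** ΔCt per well against the arithmetic mean of the reference Cts,
  ΔΔCt across groups, relative expression 2^−ΔΔCt, and a nested ANOVA whose
  group F is tested against the biological-replicate-within-group stratum.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Stage 1
generates the synthetic study into `results/sim/`; stages 2–6 run the
pipeline and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_pair_and_prioritize.R
Rscript analysis/04_functional_enrichment.R
Rscript analysis/05_network_concordance.R
Rscript analysis/06_qpcr_validation.R
```

Output from a run of stages 2, 3 and 5:

```
detected 572 miRNAs (intensities 1.0-579.6); 14 up, 9 down at |FC|>=1.2, p<=0.05
recovered 17/22 planted miRNAs; 1 features in the >=500-intensity catalog
up-miRNA group: 882 pairs over 720 unique mRNAs; tiers top=95 high=175 promising=270
down-miRNA group: 408 pairs over 371 unique mRNAs; tiers top=47 high=100 promising=135
inverse correlation of paired log2 fold changes: r = -0.967 (p = 0, n = 1290)
network: 1307 edges (17 regulator->miRNA, 1290 miRNA->mRNA)
943/1066 targets misexpressed in >= 1 perturbation dataset (88%)
79.9% of misexpressed targets concordant (planted: 80%)
```

Reading this: 17 of the 22 planted differential miRNAs are recovered (the
five misses are the 1.2–1.3-fold features, which sit at the edge of what
3 + 3 replicates can call); the retained pairs correlate at r = −0.967
because the generator suppresses true targets proportionally to their
miRNA's effect; and the planted 80% perturbation-direction agreement is
recovered as 79.9%. Equivalently, `run_pipeline()` orchestrates all stages
from one `key: value` config (see `?run_pipeline`).

Small example tables under `inst/extdata/` (a 22-feature differential table
and a 31-feature high-expression catalog with intensities between 515.4 and
15592.3) drive the documentation examples and tests.

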