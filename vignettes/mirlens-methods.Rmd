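---
title: "Methods: integrative miRNA-mRNA analysis of a lens knockout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative miRNA-mRNA analysis of a lens knockout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlens)
```

# The analysis and its assumptions

The pipeline asks a layered question about a tissue-restricted regulator of
post-transcriptional control: when the regulator is deleted, (1) which
miRNAs change abundance, (2) which predicted target mRNAs change in the
*opposite* direction, (3) which of those inverse pairs are credible for the
tissue once lens-enrichment evidence at two developmental stages is
applied, (4) what functions the candidate targets share, (5) whether a
signed regulatory network built from the pairs is directionally consistent
with independent perturbations of other lens regulators, and (6) whether
selected miRNA changes confirm by qPCR.

The substrate is a feature-by-sample matrix of non-negative microarray
intensities with two groups (knockout as *case*, littermate as *control*),
three biological replicates each. Intensities are assumed to be
feature-summarized already (probe-level processing is out of scope) and on
a linear scale; noise is treated as multiplicative, so all testing happens
on log2 intensities. Missing values are rejected rather than imputed.

## Differential miRNA calling

`quantile_normalize()` equalizes the full intensity distribution across
arrays (delegating to limma's implementation): after normalization each
sample's sorted values equal the cross-sample mean of sorted values, and
within-sample ranks are untouched. This is the between-array step of
RMA-style processing, which is all the downstream logic needs.

`differential_test()` computes per feature the group means on the intensity
scale, the signed-ratio fold change, and a two-sample t-test on log2
intensities. Two calibration choices deserve explanation:

* **Pooled variance by default.** With two or three replicates per group,
  the Welch-Satterthwaite approximation is measurably conservative: its
  true size at a nominal 0.05 is about 0.035 under homoscedastic
  log-normal noise, which would make every calibration statement about the
  test wrong by a third. The pooled-variance t is exact under those
  conditions and is therefore the default; `var_equal = FALSE` restores
  Welch for genuinely heteroscedastic data, and `shrink` interpolates each
  feature's variance toward the across-feature mean (a cheap analogue of
  moderated statistics, default off).
* **Direction thresholds.** A feature is `up` when `fc >= 1.2` and
  `p <= 0.05`, `down` symmetrically, else `unchanged`. No multiplicity
  correction enters the default call — with ~700 features and these effect
  sizes the joint |FC|-and-p filter controls false calls tightly (the
  fold-change threshold at 3 + 3 replicates is roughly a 3-sigma event for
  null features at the noise level emulated here) — but BH q-values are
  always reported so a stricter reading is available.

The signed fold-change convention (`signed_fold_change()`) reports the
ratio of the larger mean over the smaller with a sign, so magnitudes are
always >= 1 and symmetric between directions; correlations over fold
changes first map to signed log2 (`log2_signed()`), where +2-fold and
−2-fold are ±1. Rounding to one decimal happens only at report time.

`summarize_detection()` counts features whose control mean exceeds a
detection floor (default 1.0 intensity units) and bins them at edges
5/10/50/100/500 — configurable, since detection-distribution figures in
this literature rarely print their exact edges. `highly_expressed()`
catalogs features with control mean >= 500, descending, ties broken by
feature id for determinism.

## Pairing, tiers, correlation

Predictions (miRDB-style scores in [0, 100]) are kept at score >= 50,
boundary inclusive. `pair_inverse()` retains (miRNA up, target down) and
(miRNA down, target up) pairs; differentially expressed miRNAs with no map
entry are dropped with a warning, since nothing further can be said about
them. Identifiers match case-insensitively after trimming, but no fuzzy
correction is attempted — a misspelled gene symbol stays unmatched by
design. Pair counts and unique-mRNA counts are both reported at gene-symbol
level; pairs exceed unique mRNAs whenever miRNAs share targets.

Lens-enrichment flags come from per-stage tables (gene, enrichment fold
change over a body-reference pool, expression intensity): a gene is
enriched at a stage when expression >= 100 (inclusive) and enrichment
FC > 1. Whether a stricter enrichment cutoff should apply is genuinely
open; > 1 is the permissive reading and the floor is a parameter.

Tier rules are expressions over four evidence flags (`de_p4`, `de_p30`,
`enriched_p4`, `enriched_p30`) applied top → high → promising, first match
wins. The defaults:

* top: differential at both stages and enriched at both stages;
* high: differential at both stages and enriched at >= 1 stage;
* promising: differential at the primary stage and enriched at >= 1 stage.

The exact connectives are a design choice (schematic figures in this
literature show the filters but not the Boolean structure); the rule file
grammar (`tier: flag AND (flag OR flag)`) makes any other reading a
one-line change. `de_p30` is true when the later-stage table calls the gene
in the same direction as the primary stage. Tier assignment is
deterministic and row-order independent, and weakening any evidence flag
can only demote a gene (tested as a property).

`inverse_correlation()` is Pearson's r over the pairs' signed log2 fold
changes with the usual t-transform p-value. Which quantities enter such a
published correlation (fold changes, intensities, ranks) is often unstated;
log2 fold changes are adopted because they make up- and down-regulation
magnitudes commensurate. Zero variance in either vector is an error, not a
number.

## Gene-set enrichment and clustering

`term_enrichment()` is the upper-tail hypergeometric test
(`P(X >= k)` via `phyper`) against a universe that defaults to the union of
the annotation's members — not the genome — because enrichment against
genes the annotation cannot possibly return is not interpretable.
The universe is a parameter, and the choice materially shifts p-values, so
cross-study comparisons should match universes before comparing numbers.
`cluster_terms()` reimplements annotation clustering in an open form:
single-linkage merging of terms at member-gene Jaccard >= 0.5 and a cluster
score of −log10 geometric-mean member p (equivalently the mean of
−log10 p), with score > 1.0 flagging top clusters. Proprietary
kappa-statistic clustering and the conservative overlap−1 variant of the
test are deliberately not emulated; category-level results are comparable,
exact p-values are not.

## Seed sites

`scan_seed_sites()` classifies canonical sites by the standard hierarchy:
6mer = exact reverse complement of miRNA nucleotides 2–7; 7mer-m8 adds a
pair at position 8 on the 5' flank; 7mer-A1 requires an adenine opposite
position 1; 8mer is both. Each 6mer locus reports once at its strongest
type. Only Watson–Crick pairs count by default (`allow_wobble = TRUE`
admits G:U), coordinates are 0-based half-open on the supplied
sense-oriented UTR, and every reported site is re-verifiable by direct
character comparison — the test suite does exactly that with an independent
string-based scanner.

## Network and concordance

Edges are signed in the wild-type frame: a miRNA elevated after knockout is
normally repressed by the regulator (repressive edge), a reduced one is
normally activated; every miRNA→mRNA edge is repressive. The knockout-side
observation is derived, not stored, which keeps sign composition checkable:
regulator-represses-miRNA plus miRNA-represses-mRNA must equal the mRNA
being reduced in the knockout, and the tests assert this for every chain.

`concordance()` takes the network targets, a set of perturbation DE tables
and the reference directions, calls a target misexpressed in a dataset at
|FC| >= 1.2 and p <= 0.05, and counts it concordant when >= 1 misexpressed
call matches the reference direction (not all calls — "one or more" is the
operative reading). Gain-of-function datasets invert the expected direction
before comparison, flagged per dataset in the manifest. Targets absent from
every table leave the denominator; the summary reports both the
misexpressed fraction (of present targets) and the concordant fraction (of
misexpressed targets).

## qPCR

ΔCt per well is the target Ct minus the arithmetic mean of the reference
Cts in the same well-group (averaging Cts equals a geometric mean of linear
quantities; the combination rule for multiple references is rarely printed,
and this is the standard choice). ΔΔCt is the case-minus-control difference
of per-biological-replicate mean ΔCt; relative expression is 2^−ΔΔCt.
The nested ANOVA fits `dCt ~ group + bio(group)` and tests the group mean
square against the biological-replicate-within-group mean square — the
defining feature of a two-level nested design; technical replicates only
stabilize the biological means and form the residual stratum. Swapping the
group labels inverts the relative expression exactly, and the three sums of
squares always add to the total (both tested).

# The synthetic generator

`synthetic_design()` / `generate_study()` produce every input with planted
truth. Defaults emulate the study conditions this pipeline addresses:

| parameter | default | rationale |
|---|---|---|
| features | 700 miRNAs, 4000 mRNAs | detected-feature scale of a lens miRNA array and a desk-scale transcriptome |
| replicates | 3 + 3 | three biological replicates per group |
| planted miRNAs | 14 up, 8 down, effects 1.2–2.2-fold | the magnitude range such arrays report |
| planted intensities | control means 4.4–627 | differential calls live in the low-to-mid intensity range |
| noise | log-normal, sigma 0.1 (natural log) | multiplicative, keeps intensities positive |
| target map | true pairs score in [50, 100], decoys in [0, 50) | the score filter has real work to do |
| target density | 0.02 per (planted miRNA, pool mRNA) | gives ~1100–1400 unique target genes, the scale such integrations report |
| inverse effect | mRNA log2 FC = −miRNA log2 FC × e^N(0, 0.15) | proportional suppression with pair-level jitter |
| enrichment | 50% of target genes per stage | exercises every tier |
| concordance | Bernoulli(0.8) flag per target | concordant targets agree in every covering dataset, discordant in none, so the planted fraction is identifiable from the ≥ 1-same-direction summary |
| qPCR noise | shared bio 0.3, assay-level bio 0.1, technical 0.05 cycles | the shared component cancels under normalization, the assay-level one does not |

Each mRNA belongs to one direction pool (targets of up- or of down-planted
miRNAs), so planted inverse effects never conflict on a shared target.
Identical designs (including the seed) generate bit-identical files; the
RNG state of the caller is restored.

What the generator does *not* emulate: probe-level array physics, batch
effects, RNA-seq count overdispersion, correlated noise across features,
annotation bias, or miRNAs with mixed-direction target programs. Passing
the end-to-end tests therefore demonstrates that the pipeline's logic is
internally consistent and calibrated under clean multiplicative noise — not
that any particular biological dataset would reproduce.

# Numerical choices and degenerate inputs

* Zero intensities are guarded by a 1e-8 pseudo-count before log2; group
  means of exactly zero are clamped to the smallest positive double before
  the ratio.
* Features with zero variance in both groups get p = 1 when the means
  agree (and p = 0 otherwise), so flat features never enter calls.
* Detection bins are right-closed, `(floor, e1], ...`; expression and score
  floors are inclusive.
* Ranking ties (highly-expressed catalog) break by feature id; tier counts
  per gene use the gene's best tier across its pairs.
* Empty structures (no pairs, empty GMT, empty networks) are valid and
  round-trip as empty files.

# Problem sizes in the test suite

The suite checks calibration at sizes chosen to make the bands sharp but
the run quick: the null type-I check uses one 5000-feature null matrix
(3 SE band ±0.009 around 0.05), planted recovery uses three 700-feature
studies at effect 2.0, hypergeometric p is compared with exhaustive
enumeration over every instance with universe ≤ 12, nested-ANOVA null
uniformity uses 500 simulated plates, and the end-to-end run uses the full
default design (700 × 4000, ~1700 true pairs). All fixtures are generated
in code at test time.

# Known limitations

* The enrichment clustering is an open reimplementation; exact p-values
  and cluster memberships differ from proprietary annotation tools even
  when category-level conclusions agree.
* The DE test is feature-wise; no information sharing beyond the optional
  variance-shrinkage weight.
* Concordance treats perturbation datasets as exchangeable evidence; no
  weighting by dataset quality or sample size.
* Amplification-efficiency correction (Pfaffl-style) is not implemented;
  2^−ΔΔCt assumes near-100% efficiency for targets and references alike.
* UTR scanning assumes the supplied sequence is already sense-oriented;
  strand handling and cross-species conservation scoring are out of scope.
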