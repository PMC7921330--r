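Package: mirlens
Title: Integrative miRNA-mRNA Differential Expression and Network Analysis for Lens Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential microRNA calling from intensity microarrays with a
    signed fold-change convention, inverse miRNA-mRNA target pairing against a
    score-filtered prediction map, tiered candidate prioritization using
    lens-enrichment evidence at two postnatal stages, hypergeometric GO-term
    enrichment with DAVID-style cluster scoring, signed regulatory-network
    derivation with direction-concordance assessment across independent gene
    perturbation datasets, and 2^-ddCt qPCR quantification with two-level
    nested ANOVA. Includes a synthetic-data generator that plants differential
    features, true targets, enrichment and concordance so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    limma,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
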