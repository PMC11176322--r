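Package: scnamix
Title: Mixed Treatment Response Classification and Progenitor-Referenced
    Somatic Copy-Number Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying heterogeneous (mixed) responses to targeted
    cancer therapy and the somatic copy-number alterations (SCNAs) that
    accompany them. Implements lesion-level radiological response
    classification with per-patient mixed/homogeneous calls, a
    progenitor-referenced copy-number caller for clone pairs sequenced
    without a matched normal (read-depth ratios, allelic-balance SNP
    filtering, changepoint segmentation, Gaussian-mixture reference
    modelling and Z-tests), a sampling-simulation null model for recurrent
    SCNA detection across tumor cohorts, cross-species synteny projection of
    alteration frequencies, and single-cell copy-number QC filters and
    heterogeneity metrics (pairwise genome difference, Shannon evenness,
    wGII, ploidy and whole-genome-doubling summaries). A synthetic-data
    module generates every input with planted ground truth so the full
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
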