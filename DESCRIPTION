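Package: HSglycotyper
Title: Heparan Sulfate Glycotyping and Antibody Epitope Inference
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing cell-surface heparan sulfate (HS)
    modification patterns with panels of HS-specific single-chain antibody
    fragments (scFvs). Implements an 11-digit quintuplet code for HS
    disaccharides and its translation into a pseudo-amino-acid alphabet,
    IC50-weighted multiple-sequence construction and progressive alignment
    of HS oligosaccharides, position-weight-matrix and information-content
    inference of antibody-bound HS epitopes, mean-fluorescence-intensity
    (MFI) glycotype analytics (summaries, percentile heatmaps,
    control-relative normalization, high/low fractionation gates, binding
    distributions, glycotype dissimilarity), gene-signature scoring
    (signed log-p preranked statistics, top-N lineage module scores with
    housekeeping normalization, Pfaffl qPCR quantification), and seeded
    synthetic-data generators for every input so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Glycomics, FlowCytometry, SequenceMatching, Software
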