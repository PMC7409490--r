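Package: methylGEM
Title: Differential DNA Methylation and Methylation-Expression Integration
    for Tumor Subgroups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls differentially methylated regions (DMRs) from per-CpG
    bisulfite call tables under coverage, CpG-count, methylation-band,
    delta and FDR filters; calls differentially methylated cytosines (DMCs)
    from array beta tables; annotates DMRs to promoter, gene-body and
    intergenic compartments relative to the nearest TSS; classifies genes
    whose expression correlates with DNA methylation (GEMs) by intersecting
    DMR direction and compartment with two-fold expression changes; overlays
    histone-mark, super-enhancer and CTCF intervals on DMRs; and provides
    dataset-level summaries (top-variable selection, hierarchical clustering,
    PCA, subgroup composition). A synthetic cohort generator with a planted
    truth table stands in for unavailable patient data and drives
    property-based recovery tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
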