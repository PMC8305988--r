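Package: gfabric
Title: Genomic Fabric Analysis of Multi-Region Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes every gene of a multi-region, multi-replicate
    transcriptome by three independent coordinates: average expression level
    (AVE), relative expression variability across biological replicates (REV,
    a chi-square-corrected pooled coefficient of variation), and expression
    correlation (COR) with every other gene. On top of these it scores
    differential regulation with a variability-dependent fold-change cut-off
    and weighted individual/pathway regulation (WIR/WPR), classifies pairwise
    expression coordination (synergism, antagonism, independence), ranks genes
    by Gene Commanding Height (GCH) to identify each region's Gene Master
    Regulator (GMR), and forecasts the transcriptomic consequences of
    overexpressing a master regulator. Includes spot-level microarray
    ingestion (quality filtering and iterative median normalization) and a
    synthetic study generator with planted ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    fgsea
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
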