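Package: cenrich
Title: Restriction-Based Centromere Enrichment Prediction and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the enrichment of centromeric and pericentromeric
    satellite DNA achievable by multi-enzyme restriction digestion followed
    by fragment size selection. Performs in silico digestion of reference
    genomes with panels of restriction enzymes carrying degenerate (IUPAC)
    recognition sites, summarises fragment-length distributions by genomic
    origin, screens enzyme combinations for high predicted enrichment, and
    quantifies realised enrichment from sequencing-derived inputs: k-mer
    based satellite read classification, binned log2 enrichment profiles and
    enrichment-domain calling, uncut-site quantification, and per-CpG
    methylation-frequency comparison between conditions. A synthetic-data
    module generates tandem-repeat toy genomes, size-selected read pools and
    methylation call tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
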