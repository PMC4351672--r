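Package: termloop
Title: Protein Binding at Transcription Termination Regions and Regional
    Mutation Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-scale analysis of ChIP-seq peak binding at transcription
    termination regions (TRs) and its relation to R-loops and to
    region-restricted somatic mutation burden in tumour cohorts. Builds
    strand-aware TR, promoter, whole-gene and TTS-window regions from gene
    models; tests peak-region overlap enrichment against a uniform-placement
    analytic null and a chromosome-aware shuffle null; compares expression and
    DRIP (R-loop) signal between gene groups with rank tests; and quantifies
    regional mutation enrichment between tumour groups with a stratified
    one-tailed Cochran-Mantel-Haenszel Z statistic. A synthetic-data module
    generates genomes, peaks, expression tables, coverage tracks and
    per-patient mutation catalogs with planted, parameterised structure so the
    whole pipeline can be validated closed-loop without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
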