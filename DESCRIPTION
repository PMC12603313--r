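Package: miraux
Title: miRNA-Guided Auxin Signalling Modules from Transcriptome, Degradome and Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Integrated identification and functional curation of miRNA-regulated
    auxin nuclear-signalling components in plant transcriptomes. Finds complete
    open reading frames, classifies candidate TIR1/AFB auxin receptors (F-box,
    LRR coverage, binding-pocket and adenylate-cyclase residue conservation) and
    ARF transcription factors (B3 DNA-binding motif, middle-domain composition,
    PB1 motif typing), validates miRNA precursors by stem-loop folding and
    precursor-miRNA expression correlation, confirms miRNA target sites against
    degradome 5'-end tags with the standard category ladder and T-plot export,
    and provides FPKM/RPM/Z-score normalisation, 2^-ddCt relative expression and
    ANOVA/Tukey group comparisons. A seeded synthetic-data generator produces
    every input with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
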