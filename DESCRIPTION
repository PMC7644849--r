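Package: promscan
Title: Promoter Motif Scanning with Chromatin-State Filtering and
    Expression Quantification
Version: 0.1.0
Authors@R:
    person("Promscan", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maps candidate transcription-factor binding sites in
    promoter regions by position-weight-matrix scanning of 10-kb
    upstream-of-start-codon windows against JASPAR-format motif models,
    retains sites above a relative ("potential match") score threshold,
    and filters them by histone-mark chromatin state and ChIP-seq
    cluster evidence.  Surviving sites are reduced to per-gene
    transcription-factor sets and compared across promoters as Venn
    partitions.  Companion quantification utilities implement
    comparative threshold-cycle (delta-delta-Ct) relative expression,
    expression-morphology time-course correlation, dual-luciferase fold
    change, and peroxisome morphology categorisation from particle
    length tables.  A synthetic-data generator plants motif instances at
    controlled relative scores with matched chromatin tracks and known
    ground truth, so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
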