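Package: neuromir
Title: miRNA Profiling and miR-10 Target Inference in Regionalized Neural
    Progenitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for small-RNA expression profiling of
    regionalized human neural progenitor cells. Turns small-RNA FASTQ reads
    into mature-miRNA count matrices by adapter trimming, length filtering,
    read collapsing and exact-match assignment; normalizes counts to equal
    totals and selects progenitor-enriched miRNAs relative to embryonic stem
    cells; summarizes miRNA-family pool fractions per cell group; analyzes
    targeted qPCR panels (dCq normalization, high-variance feature selection,
    per-feature one-way ANOVA across age groups, centred group profiles, and
    delta-delta-Ct relative quantification); and infers miRNA target genes
    from paired overexpression/control mRNA counts via fold-change
    cumulative-distribution shifts (two-sample Kolmogorov-Smirnov test) and
    cross-condition intersection. A synthetic-data module generates all
    pipeline inputs with known ground truth so every stage can be validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
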