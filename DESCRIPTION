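Package: methnome
Title: Differential Methylation, Nucleosome Occupancy and 5hmC Analysis
    for WGBS and NOMe-seq Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Count-level analysis of whole-genome bisulfite (WGBS) and
    NOMe-seq experiments for two-group comparisons such as
    monocyte-to-macrophage differentiation. Implements quality-filtered
    methylation calling with trinucleotide context classification
    (HCG/GCH/GCG/HCH), kernel-smoothed differential methylation region
    (DMR) detection, nucleosome-depleted region (NDR) calling by a
    two-state binomial hidden Markov model with Fisher flank contrasts
    and shuffle-based empirical false-discovery rates, matched
    random-region permutation enrichment for annotation overlap,
    DMR-versus-peak overlap classification, 5-hydroxymethylcytosine
    estimation from paired BS/oxBS counts, and k-means clustering of
    binned ChIP/input histone signatures at DMRs. A synthetic-data
    module generates toy genomes and count tables with planted ground
    truth so every stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
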