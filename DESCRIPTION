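Package: hexmeth
Title: Methylation Diversity Analysis for Allohexaploid Wheat Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for analysing DNA methylation diversity across
    panels of allohexaploid wheat accessions profiled by targeted bisulfite
    sequencing. Starting from per-cytosine count tables and per-accession
    SNP calls, it identifies single methylation polymorphisms (SMPs),
    classifies subgenome-resolved (uni-/bi-/tri-genome) methylation via
    indel-aware homoeolog coordinate translation and Fisher exact contrasts,
    calls differentially methylated regions in 100-bp windows, quantifies
    deamination-driven C-to-T enrichment at ancestrally methylated
    cytosines, compares epigenetic and genetic population structure
    (hierarchical clustering, multiscale-bootstrap cluster support, Mantel
    and runs tests, geographic concordance), links promoter methylation to
    homoeolog expression balance, and profiles transposable-element family
    abundance. A fully specified synthetic hexaploid panel generator with
    recorded ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    vcfR
Config/testthat/edition: 3
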