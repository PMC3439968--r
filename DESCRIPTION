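Package: iclipr
Title: Crosslink-Site Calling, Motif and RNA-Map Analysis for iCLIP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing individual-nucleotide-resolution UV
    crosslinking and immunoprecipitation (iCLIP) data: deduplication of
    aligned CLIP-tags by random barcode (UMI), assignment of crosslink
    sites to the nucleotide upstream of each tag start, permutation-based
    false discovery rates for crosslink sites and CLIP-tag clusters,
    pentamer Z-score motif enrichment with within-gene shuffled nulls,
    length-normalized positional metaprofiles (RNA maps) around splice
    sites, branch points and transcript anchors, and RNA-class density
    enrichment. Includes a fully seeded synthetic-data generator that
    emits genomes, annotations, branch-point candidate tables and
    simulated CLIP-tags with known ground truth, so every stage of the
    pipeline can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
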