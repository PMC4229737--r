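Package: vblock
Title: Variation-Block Detection, Typing and Marker Selection for
    Resequenced Crop Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects recombination-derived variation blocks in resequenced
    crop genomes from per-sample variant calls: homozygous-SNV density
    binning, two-pass merging into dense and sparse variation blocks,
    genome partitioning by the pooled block boundaries of a sample set,
    block typing by variant-level sequence identity and SNV-set
    concordance, parental-origin mapping, block-level diversity curves,
    and selection of block-representative indel markers for hierarchical
    single-marker trait screens. Includes a breeding-genome simulator
    (founder haplotype mosaics, crossover-biased crosses, recombinant
    inbred line populations, depth-dependent SNV dropout) with full truth
    tracks, and an evaluation harness scoring detected blocks against
    truth at base-pair resolution.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    vcfR,
    IRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
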