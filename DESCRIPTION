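Package: popgenscan
Title: Windowed Genome Scans for Balancing Selection and Divergent Sorting
    of Ancestral Polymorphisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Windowed population-genomic scans over multi-sample SNP data:
    within-population diversity statistics (pi, Watterson's theta, Tajima's D,
    Fay and Wu's H), between-population divergence (Weir-Cockerham weighted
    FST as a ratio of averages, dXY, da, RND), Z-score outlier screens with
    island calling and region merging, randomization tests, demographically
    informed coalescent null distributions, site-frequency-spectrum
    downsampling, isolation-by-distance regression and linkage-disequilibrium
    decay. Includes a structured-coalescent synthetic-data generator that
    emulates balanced and divergently sorted ancestral haplogroups, inbred
    genotypes and a sequencing depth/error layer, so that every stage of the
    scan is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    GenomicRanges,
    IRanges,
    geosphere,
    minpack.lm,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
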