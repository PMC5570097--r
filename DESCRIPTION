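Package: fermentome
Title: Dual-Platform Profiling of Wine-Fermentation Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling fungal communities in fermenting grape must
    by two complementary sequencing strategies: ITS meta-barcoding (quality
    trimming, pair merging, inline-barcode demultiplexing, md5-keyed
    dereplication, single-linkage OTU clustering and consensus taxonomy
    assignment) and reference-based shotgun metagenomics (host filtering,
    read mapping, 10-kb genomic windowing with per-window read counts and
    mean read identity, and breadth-filtered species abundance summaries).
    Includes a synthetic mock-community generator with controllable
    cell counts, ribosomal ITS copy numbers and taxon-specific amplification
    bias, so that the cross-platform observed/expected ratio analysis that
    exposes ITS amplicon bias can be exercised end-to-end with known ground
    truth, plus Bray-Curtis dissimilarity and principal-coordinate analysis
    of community structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    openssl,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    vegan,
    ape,
    jsonlite,
    optparse,
    digest,
    withr
Config/testthat/edition: 3
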