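Package: wormbridge
Title: Gene Lineage Conversion and Cross-Platform Infection Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing Caenorhabditis elegans transcriptome data sets
    produced against different annotation releases and on different platforms.
    Converts gene identifier lists between annotation releases by replaying
    recorded merge/split/kill/rename events, reports every change, and detects
    the most likely source release of a list. Quantifies expression from tiling
    arrays (PM-MM signal, quantile normalization, pseudomedian smoothing,
    exon-overlap assignment) and from RNA-seq per-base coverage (depth of
    coverage per million mapped reads). Calls up- and down-regulated
    transcripts by a percentile fold-change rule and by two geometric methods
    that widen their acceptance envelope at low expression, flags
    infection-specific transcripts, builds platform base sets, intersects gene
    sets across platforms and pathogens, selects biomarkers, tests peptide
    length and conservation enrichment, and performs EASE-style category
    overrepresentation analysis with release-aware refreshing of category
    databases. Includes seeded generators for synthetic annotation histories,
    heteroscedastic paired expression tables, probe intensities and coverage
    tracks with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    limma,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
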