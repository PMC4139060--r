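Package: stairstep
Title: Broad Chromatin Domain Calling and Boundary Detection from
    ChIP-seq Fragment Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for calling broad histone-modification domains
    (e.g. H3K27me3) from paired-end ChIP-seq fragment intervals and for
    locating the sharp domain boundaries that appear when successive cell
    populations lose the mark over nested spans of a locus. Implements
    input-normalized positional coverage, sliding-window enrichment scored
    against an empirical null built from randomly placed tags,
    replicate-intersected region calls, cross-condition differential
    density via line-of-fit Z-scores, run-based covered/clear
    segmentation with boundary calling, Gaussian-smoothed
    input-subtracted profiles, and a synthetic fragment generator that
    plants nested clear domains with tunable anterior contamination for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
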