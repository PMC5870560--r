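Package: dynatrack
Title: Dynamic Track Selection, Grouping and Carousel Browsing for Genomic Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless engine for dynamic genome-browser track management.
    Hundreds of quantitative signal datasets, each registered together with
    its companion feature dataset (peak list), are compiled into a single
    queryable interval index; for any genomic window the engine classifies
    tracks as locus-specific interesting or empty, composes an ordered track
    container honouring group contiguity, predefined within-group order,
    anchoring below static tracks, and per-group and global visibility caps,
    and rotates carousel views cyclically through overflowing groups. Ships
    a deterministic synthetic-fixture generator, a navigation-script replay
    runner with canonical JSON state output, a static SVG renderer of the
    composed view, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Visualization, GenomeBrowsers, Epigenetics
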