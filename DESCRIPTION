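Package: pulscan
Title: Polysaccharide Utilization Locus Detection and Dispersed
    Laminarin-Utilization Gene Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects polysaccharide utilization loci (PULs) in annotated
    bacterial genomes by a windowed SusC/D-pair rule, builds consensus
    CAZyme and SusC/SusD annotations from multi-tool domain-hit tables,
    classifies GH16 laminarinase domain architectures and sequence motifs,
    and quantifies the dispersion of pathway gene sets. Also implements the
    surrounding measurements: an s0-moderated permutation-FDR t-test for
    label-free quantitative proteomics, a fluorescent-substrate uptake
    scorer for two-channel microscopy, and growth-rate, cell-density and
    enzyme-activity quantifications. Ships seeded synthetic-data generators
    emulating every input so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    GenomicRanges,
    jsonlite,
    methods,
    png,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
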