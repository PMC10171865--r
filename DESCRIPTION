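Package: apicodyn
Title: Quantification of Pulsed Apical Constriction and Junctional
    Anisotropy in Segmented Epithelia
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of tracked label-image time series of epithelial
    apical surfaces: signed contraction/shrinkage rate series,
    detection of ratchet-like constriction pulses against a
    mean-plus-one-SD reference threshold, constriction-period and
    ingression-event annotation with a 30-minute isolated-versus-
    clustered rule, asynchronous per-junction shrinkage statistics,
    and fixed-tissue junctional intensity quantification (per-cell
    anisotropy by SD and Max/Min ratio, planar-polarity nematics,
    orientation binning, and pairwise channel correlation with
    low-intensity filtering). Includes a seeded synthetic generator
    of segmented epithelial tissue (Lloyd-relaxed Voronoi meshes,
    programmed constriction pulses, junction shrink schedules,
    clustered ingression plans, and painted junctional channels with
    configurable anisotropy, reciprocal enrichment, and planar
    polarity) with machine-readable ground truth, so every stage of
    the pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: CellBiology, Software, Visualization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
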