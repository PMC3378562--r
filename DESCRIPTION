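Package: emrecon
Title: Serial-Section Electron Microscopy Volume Reconstruction and
    Circuit Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for composing deformed two-dimensional electron
    microscopy image tiles into coherent volumes and extracting neuronal
    circuits from them. Covers feature-based montaging of overlapping
    tiles, global pose optimization across sections, block-matching plus
    spring-mesh elastic alignment, composed rendering of image regions
    with alpha masks and composite modes, confidence-weighted skeleton
    annotation of neuronal arbors, polyadic synapse connectors,
    ontology-constrained project trees, area-list volumetry with
    iso-surface meshing, stereological counting, and exchange formats
    (SWC, NeuroML, adjacency tables). A deterministic synthetic-data
    generator provides ground-truth fixtures for every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    xml2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
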