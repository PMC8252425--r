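Package: cortimorph
Title: Morphometry and Innervation Analysis of the Organ of Corti
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of skeletonized volume-electron-microscopy
    annotations of the cochlear outer-hair-cell region. Reads webKNOSSOS-style
    NML and SWC skeletons plus synapse tables, builds a basilar-membrane
    reference frame from Deiters-cell roots, measures Y-shaped outer hair cell
    (OHC) and Deiters cell (DC) complexes (lengths, SVD principal axes,
    intersection angle alpha, longitudinal angles beta, reticular-lamina mosaic
    span), profiles type-2 spiral ganglion neuron trajectories (biphasic
    climbing/contact slope fits, per-support heights, row-specific innervation)
    and classifies medial olivocochlear efferent fibers by tunnel-crossing
    count. A seeded parametric generator emulates the organ-of-Corti lattice
    and its innervation with a ground-truth ledger, so every analysis stage is
    testable without the electron-microscopy volume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
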