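Package: ersfviz
Title: Enhanced Radial Space-Filling Layouts for Ontology DAGs and Tiered
    Pathway Scenes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes Enhanced Radial Space-Filling (ERSF) sunburst layouts
    for ontology directed acyclic graphs, drawing each term as a nested
    annular region on the spanning tree of major-parent edges and every
    multiple-inheritance (non-tree) edge as a satellite orbit with a radial
    downlink ray and access points.  Gene-level experimental values are
    aggregated onto ontology terms (mean, median, coefficient of variation,
    differential-expression counts and one-sided Fisher/hypergeometric
    overrepresentation) and mapped to region color, extrusion height and
    transparency, including per-condition animation frames.  Also provides a
    3D aligned tiered layout for typed pathway graphs (one plane per entity
    type, aligned to a user-chosen major plane) and renderers to SVG and KML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
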