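Package: divtime
Title: Batch Management and Analysis of Pairwise Species Divergence Times
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for assembling, validating and analysing pairwise
    divergence-time data over species lists: conversion between long-format
    ("vectorized") pair tables and square divergence matrices, CSV input and
    output, detection and repair of missing values, a pluggable retrieval
    backend with a packaged offline fixture implementation, Magallon-Sanderson
    crown-age net diversification rate estimators with and without extinction,
    ultrametric time-tree utilities (Newick input and output, MRCA-age matrix
    extraction, UPGMA reconstruction, crown age, ASCII preview), Mantel tests
    and Mantel correlograms for comparing divergence time to genetic distance,
    and both a menu-driven and a scriptable command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    e1071,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
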