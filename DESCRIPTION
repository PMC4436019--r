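Package: pathburst
Title: Orthology-Based Pathway Projection, Crosstalk Detection and Sunburst Rendering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects a Reactome-style pathway hierarchy onto target species
    through ortholog maps, classifying every pathway as complete, partial or
    empty; detects pathway crosstalk through gene products shared between
    pathways at a hierarchy level; overlays differential-expression data as
    per-pathway up/down counts and DE ratios; encodes magnitudes with
    order-of-magnitude markers (dual wide/narrow bars for exponent and
    mantissa); and lays the hierarchy out as a radial sunburst rendered to
    static SVG. Ships deterministic synthetic generators for hierarchies,
    ortholog maps, expression tables and rate-limiting annotations, plus a
    command-line interface over the same functions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    stats,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
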