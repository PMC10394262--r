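Package: gallerytrack
Title: Measure Length Development of Animal-Built Gallery Systems from
    Traced Image Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the temporal development of gallery
    systems built by animals (termite foraging tunnels, ant nest
    excavations, mouse burrows) from sequences of images annotated as
    polylines. Traced galleries are aligned to a per-image reference
    point, calibrated from pixels to millimetres with a scale object,
    classified into primary/secondary/tertiary identities by branching
    rules, and reduced to a network of entrance, intersection and end
    nodes with measured edges. Skipped images inherit the previous
    annotation, empty images yield zero records, and an append-mode
    check flags galleries that shrink over time. Results are exported
    as tidy per-image, per-gallery, node and edge tables plus overlay
    renderings, and a seeded synthetic growth generator provides ground
    truth for testing without real photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble
Suggests:
    igraph,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
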