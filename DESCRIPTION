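Package: wcpipe
Title: Semi-Automated Target Detection and Classification in Multibeam
    Water-Column Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for detecting and classifying water-column
    targets (fish schools, gas seeps, platform structures and acoustic noise)
    in multibeam echosounder water-column imagery. Provides a labelled survey
    simulator with realistic two-transducer fan geometry, stacked-beam
    echogram cleaning (median, erosion and dilation convolution filters,
    bad-ping rejection, bottom and surface virtual lines), per-beam bottom
    detection with a resampled seafloor TIN, per-ping connected-component
    target segmentation into polygon slices extruded to 0.8 m polyhedra,
    proximity-based multi-ping region tracking, a 24-metric slice feature
    schema, and a semi-supervised classifier combining label extension,
    k-nearest-neighbour pseudo-labelling and a grid-searched gradient-boosted
    ensemble with transfer prediction to unseen surveys.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    car,
    igraph,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    class
Config/testthat/edition: 3
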