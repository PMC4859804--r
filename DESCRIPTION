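Package: topoflat
Title: Flatmap-Based Quantification of Topographic Axonal Projections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the topographical organization of axonal projections
    mapped by anterograde tract tracing across development. Injection sites
    are transposed onto a triangulated pial surface of the source area and
    expressed as normalized rostrocaudal and dorsoventral coordinates;
    per-animal section measurements of the target region are combined into an
    age-normalized average flatmap of square bins; labeled-fiber and
    dense-plexus observations are binned onto that flatmap, normalized,
    pooled, and summarized by centers of mass; and topography is tested with
    k-means clustering of smoothed flatmaps and multiple regression with
    backward elimination of two-way interactions. A seeded synthetic-study
    generator emulates the measurement tables, injections and topographically
    graded labeling so the full pipeline is testable without histological
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
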