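Package: flaviclim
Title: Climate-Flavonoid Chemometrics with GA-Initialized Backpropagation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reproducible pipeline linking monthly climate factors to
    flavonoid content and antioxidant activity of plant extracts. Implements
    colorimetric total-flavonoid and radical-scavenging assay arithmetic with
    log-linear IC50 estimation, accurate-mass flavonoid annotation
    (monoisotopic masses, ESI adduct m/z, ppm/mDa errors, candidate-formula
    enumeration with an RDBE filter, UV lambda-max matching against a bundled
    reference library), a genetic-algorithm-initialized backpropagation
    network with min-max input scaling and one-at-a-time climate-factor
    sensitivity analysis, and verification statistics (Pearson correlation
    banding, correlation-matrix PCA, agglomerative hierarchical clustering).
    A seeded synthetic-data generator with planted ground truth makes every
    stage testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
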