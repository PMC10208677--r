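Package: photopace
Title: Analysis of Light-Paced Cardiac Muscular Thin Film Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipelines for quantifying photostimulated cardiac tissue on
    muscular thin film (MTF) cantilevers. Converts cantilever bending movies
    into film stress traces via the Stoney relation and circular-arc
    projection geometry, extracts twitch statistics (diastolic, systolic and
    twitch stress, contraction frequency), reconstructs calcium activation
    maps and conduction velocities from optical-mapping movies, computes
    axial circular statistics of nuclear orientation, and handles stimulus
    train and protocol accounting. A seeded forward-model simulator renders
    synthetic cantilever and calcium movies with known ground truth so every
    inverse pipeline is verified by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
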