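Package: larvatrack
Title: Individual-Level Tracking and Behavioural Phenotyping of Drosophila Larvae
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tracks individual Drosophila melanogaster larvae through videos of
    freely crawling groups while preserving identities across collisions, and
    derives a catalogue of behavioural attributes per animal. The pipeline
    covers background subtraction and Otsu segmentation, contour and spine
    reconstruction, collision-graph construction with larva counts solved by
    linear programming, shape-model and statistical collision resolution,
    detection of peristaltic steps, lateral head casts, runs and
    forward/backward switches, per-larva attribute tables, random-forest
    phenotyping and a nonparametric test battery. A kinematic scene simulator
    with frame-level ground truth makes the whole pipeline testable without
    real videos.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
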