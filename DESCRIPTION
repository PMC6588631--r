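Package: histoquery
Title: Content-Based Image Retrieval for Histopathology Patches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reverse image search for histopathology image patches. Builds an
    orientation-augmented embedding database from tiled whole-slide images
    (eight dihedral orientations per 300x300 patch, 128-dimensional vectors),
    retrieves nearest neighbours by exact L2 search over a k-d tree with
    per-patch orientation deduplication and a spatial-diversity filter, and
    ships the full evaluation machinery: balanced study subsampling, top-5
    scoring, confusion matrices, blinded rater-study rubrics, and the
    associated statistics (exact McNemar, Mann-Whitney U, Clopper-Pearson
    intervals). A seeded generator of classed texture patches and pyramidal
    slides makes every component testable without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
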