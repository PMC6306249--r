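Package: shapecue
Title: Auditing Image Classifiers for Global-Shape Versus Local-Contour Cues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to probe whether an image classifier recognises objects by
    global shape or by local contour features. Implements a contour geometry
    engine (subpixel boundary extraction, arc-length resampling, curvature
    profiles, elliptic Fourier shape descriptors), generators for the classic
    shape-diagnostic stimulus families (silhouettes, outlines, texture
    chimeras, part-scrambled and serrated figures), seeded synthetic
    shape/texture catalogs, two toy classifiers embodying the competing
    local-feature and global-shape hypotheses, and the classification and
    psychophysics metrics (label rank, top-k, shape/texture preference,
    condition accuracy tables, pooled t tests) needed to score any classifier
    that emits a probability vector over a fixed label vocabulary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
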