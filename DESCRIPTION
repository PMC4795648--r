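Package: holoface
Title: Neural Tuning Size and Holistic Face Processing in a Hierarchical
    Visual Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates holistic face perception with a four-layer
    feedforward model of the ventral visual stream (oriented Gabor
    filtering, local max pooling, Gaussian radial-basis template
    matching, and global max pooling).  Face-selective templates are
    learnt as stored patterns of mid-level responses at three spatial
    tuning sizes, and the package runs the three classic psychophysics
    paradigms -- the composite face effect, the face inversion effect
    and the whole-part effect -- on synthetic, part-structured face
    stimuli, with paired bootstrap and Wilcoxon signed-rank inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
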