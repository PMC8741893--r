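Package: gandecode
Title: Simulated fMRI Decoding of Perceived Images via a Generative Latent Space
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end simulation and analysis framework for latent-space
    neural decoding of perceived images. Provides a seeded procedural image
    generator whose latent codes are known a priori, a simulated event-related
    fMRI experiment (trial schedule, linear latent-to-voxel encoding, BOLD
    synthesis with the canonical haemodynamic response), first-level GLM
    deconvolution with t-to-z standardisation and amplitude-based voxel
    selection, an affine response-to-latent decoder trained by adaptive-moment
    minimisation of Euclidean loss (with a closed-form ridge oracle and an
    eigenface baseline), and an evaluation suite covering latent, feature and
    pixel similarity metrics, permutation significance testing, semantic
    attribute decoding, and repetition-reliability classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    e1071,
    optparse,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
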