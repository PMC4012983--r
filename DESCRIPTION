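Package: topofa
Title: Topographic Factor Analysis of Functional Brain Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits topographic factor analysis (TFA), a Bayesian latent-source
    model that explains each image in a functional MRI series as a noisy
    weighted sum of K spherical Gaussian radial-basis-function sources.
    Inference uses black-box stochastic variational inference with
    score-function gradients, control variates, adaptive per-parameter
    learning rates, and image- and voxel-level subsampling, together with a
    deterministic hotspot initialization of source centers and widths.
    Includes source-network inference from weight covariance with split-half
    reliability and permutation testing, cross-validated selection of the
    number of sources via held-out covariance prediction, synthetic-data
    generators matching the model's generative process, NIfTI input/output,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    RNifti,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
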