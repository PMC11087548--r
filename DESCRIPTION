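Package: coinfoPE
Title: Synergistic and Redundant Coding of Prediction Errors in Cortical Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Information-theoretic analysis of auditory prediction-error (PE)
    coding across cortical areas. Implements a bias-corrected Gaussian-copula
    mutual-information (MI) estimator between continuous neural responses and a
    binary stimulus class, co-information charts (temporal and spatio-temporal)
    that decompose paired signals into redundant and synergistic components,
    permutation maximum-statistics control of the family-wise error rate,
    event-related-potential and spectral-PCA broadband signal extraction,
    multivariate co-information via cross-validated linear-discriminant decision
    values, a brain-constrained six-area leaky-integrator oddball network
    simulator with architecture ablations, and SSIM-based chart comparison with
    shuffle surrogates. Synthetic generators with analytically known ground
    truth (Gaussian trial ensembles, roving-oddball and local/global tone
    grammars) make the whole pipeline testable without real recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
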