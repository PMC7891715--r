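Package: pcnmf
Title: Periodicity-Coded NMF for Soundscape Source Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for retrieving ecological information from long-duration
    passive acoustic recordings. Builds long-term spectral averages (LTSA)
    from fixed-duration audio clips, prewhitens them against a percentile
    noise floor, and separates the mixture into sound sources with a
    two-layer periodicity-coded nonnegative matrix factorization (PC-NMF):
    the first layer learns sparseness-constrained spectral features and
    temporal activations, the second groups features into sources by the
    periodicity of their activations. Separated channels feed analyses of
    acoustic phenology (time-lagged correlations, diurnal, lunar and
    seasonal cycle models) and acoustic diversity (event detection, PCA and
    k-means clustering of event spectra). Includes a synthetic soundscape
    generator with ground truth for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    signal,
    zoo,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
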