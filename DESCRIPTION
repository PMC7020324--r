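Package: mirfuse
Title: Multi-Block FT-MIR Chemometrics for Mushroom Species Discrimination
    and Total-Polyphenol Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for Fourier-transform mid-infrared (FT-MIR) fingerprinting
    of mushroom fruiting bodies analysed as two morphological blocks (cap and
    stipe).  Implements spectral pretreatments (Savitzky-Golay smoothing and
    derivatives, multiplicative scatter correction, standard normal variate,
    1-2 min-max normalisation), deterministic Kennard-Stone partitioning,
    low-level and mid-level multi-block data fusion (principal-component,
    latent-variable and VIP feature selection), NIPALS PLS2 discriminant
    analysis with cross-validated diagnostics, RBF-kernel SVM classification
    and epsilon-regression tuned by exhaustive grid search or particle swarm
    optimisation, exact t-SNE visualisation with confidence ellipses,
    Folin-Ciocalteu total-polyphenol quantification in gallic-acid
    equivalents, and a synthetic-spectra generator so the whole pipeline can
    be exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    signal,
    cluster
Config/testthat/edition: 3
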