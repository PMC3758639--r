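Package: hica
Title: Hierarchical Independent Component Analysis for Early Visual
    Feature Learning in Underwater Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns Gabor-like bases and higher-layer texture features from
    image corpora by a recursive pipeline of 1/f pre-whitening, PCA
    whitening, fixed-point (FastICA) independent component analysis with
    deflation, and a generalized-Gaussian Gaussianization nonlinearity that
    feeds each layer's rectified responses to the next.  Includes a
    log-domain homomorphic enhancement filter merged with an orthogonal
    wavelet decomposition (with bivariate interscale shrinkage) for
    underwater images, a physics-based underwater degradation simulator
    (exponential attenuation, backscatter, forward scatter, marine snow),
    and seeded synthetic-data generators with blind-source-separation
    evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff
Config/testthat/edition: 3
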