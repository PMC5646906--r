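Package: spikegp
Title: Bayesian Intensity Estimation for Calcium Spike Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models heterogeneous calcium spike sequences as realisations of
    inhomogeneous renewal point processes (Poisson, Gamma and inverse-Gaussian
    inter-spike-interval families) conditioned on a latent intensity function.
    The intensity is inferred by MAP estimation under a squared-exponential
    Gaussian-process prior, with hyperparameters marginalised over a grid via
    Laplace-approximated evidence weights, yielding pointwise 95% credible
    bands. Includes time-rescaling goodness-of-fit diagnostics
    (Kolmogorov-Smirnov and quantile-quantile constructions with slope
    summaries), three surrogate spike-sequence generators, kernel-smoothing
    and PSTH rate baselines with data-driven bandwidth selection, a
    stimulus-clustering pipeline (SVD weights plus k-means) with a histogram
    overlap distance, and fluorescence trace normalisation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
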