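Package: ssmca
Title: Nonlinear Spike-and-Slab Sparse Coding for Occlusion-Rich Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sparse coding of image patches under a spike-and-slab
    (Bernoulli-Gaussian) prior and a pointwise-maximum combination of
    nonnegative dictionary elements, an occlusion-aware alternative to the
    linear superposition of standard sparse coding. Parameters are learned
    by truncated expectation-maximization: the E-step draws exact Gibbs
    samples from each latent's piecewise-Gaussian conditional posterior
    (with a point mass at zero) by inverse-transform sampling, restricted
    per data point to the latents preselected by cosine similarity; the
    M-step applies closed-form updates built from max-restricted and
    nonzero-restricted posterior expectations. Includes generators for
    model-drawn overlapping-bars data and opaque occluding-stroke images
    with ground-truth complexity labels, reconstruction and
    sparsity-versus-complexity evaluation, prior/posterior consistency
    checks, and an adapter to an online l1 dictionary-learning baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
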