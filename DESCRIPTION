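Package: dtnlm
Title: Non-Local Means Denoising of Diffusion Tensor Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Denoises diffusion tensor imaging (DTI) data directly in the
    space of symmetric positive-definite (SPD) matrices. Non-local means
    (NLM) weights are computed from Euclidean, affine-invariant Riemannian,
    or Log-Euclidean tensor distances and averaging is performed as the
    log-domain geometric mean, so filtered tensors remain SPD. Includes a
    synthetic sinusoid-fiber phantom generator, Stejskal-Tanner
    diffusion-weighted signal simulation with Rician noise, linear
    least-squares tensor estimation, baseline filters (component-wise
    Gaussian smoothing in tensor space and unbiased NLM in
    diffusion-weighted image space), and an evaluation suite measuring
    angular deviation of the principal direction, fractional anisotropy
    deviation, and permutation-based tensor uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
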