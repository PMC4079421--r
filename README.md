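# dtnlm — non-local means denoising of diffusion tensor fields

`dtnlm` denoises diffusion tensor imaging (DTI) data directly in the space
of 3×3 symmetric positive-definite (SPD) matrices, for researchers working
on diffusion MRI processing and on filtering methods for manifold-valued
images. Instead of smoothing each diffusion-weighted image (DWI) volume
separately, the filter operates once on the fitted tensor field: every
voxel is replaced by a similarity-weighted **geometric mean** of its search
window,

    D(p) <- exp( sum_q w(p,q) * log D(q) ),
    w(p,q) ∝ exp( -d²(p,q) / h² ),

where `d` is a distance between tensors. Because the averaging happens in
the matrix-log domain, the output is SPD by construction. Three distances
are available for the weighting:

| metric | formula | invariance |
|---|---|---|
| Euclidean | ‖D_p − D_q‖_F | rotation |
| Riemannian | sqrt(Σ ln² λ_i(D_p⁻¹ D_q)) | affine (any congruence) |
| Log-Euclidean | ‖log D_p − log D_q‖_F | rotation + scaling |

The package also provides everything needed to study the filter
quantitatively: a sinusoid-fiber phantom generator with exactly prescribed
trace and fractional anisotropy (FA), Stejskal–Tanner DWI simulation with
Rician noise, linear least-squares tensor fitting, two baselines
(component-wise Gaussian filtering in tensor space, unbiased NLM in DWI
space), principal-direction (PD) and FA deviation scoring, and a
permutation-based tensor uncertainty analysis. Tensor volumes are read and
written as 6-component NIfTI (lower-triangular order Dxx, Dxy, Dyy, Dxz,
Dyz, Dzz) with FSL-style bval/bvec files.

## Worked example

Generate the phantom (fiber trace 2.1×10⁻⁵ cm²/s, FA 0.8), simulate
32-direction DWIs at b = 1000 s/mm², corrupt with 5 % Rician noise, refit,
and denoise with Log-Euclidean weighting:

```r
library(dtnlm)

ph   <- generate_phantom(phantom_spec())
gtab <- default_gradient_table()                    # 32 dirs + 1 b0
dwi  <- add_rician_noise(simulate_dwi(ph, gtab, s0 = 1),
                         sigma = 0.05, seed = 7)
noisy <- fit_tensor_lls(dwi)

evaluate_field(noisy, ph)
#> evaluation: mean PD deviation 2.3680 deg (391 voxels), mean FA deviation 0.0355 (391 voxels)

led <- denoise_nlm(noisy, nlm_config(metric = "log_euclidean"))
evaluate_field(led, ph)
#> evaluation: mean PD deviation 1.5224 deg (391 voxels), mean FA deviation 0.0328 (391 voxels)
```

The filter recovers about a degree of principal-direction accuracy over
the 391 fiber voxels. `run_experiment()` runs all six methods on one noisy
realization and tabulates both scores:

```r
run_experiment(experiment_config(seed = 1))$report
#>              method mean_pd_deviation mean_fa_deviation
#> 1             noisy             2.492           0.03388
#> 2          gaussian             1.178           0.10465
#> 3     nlm_euclidean             1.521           0.02222
#> 4    nlm_riemannian             1.519           0.03391
#> 5 nlm_log_euclidean             1.533           0.03195
#> 6          unlm_dwi             1.405           0.02694
```

Every denoiser improves the PD; the Gaussian baseline pays for its
smoothing with a large FA error at the fiber edges. See the vignette
(`vignettes/tensor-space-nlm.Rmd`) for the model, parameter guidance, and
design notes.

A thin command-line front end with subcommands (`phantom`, `simulate`,
`noise`, `fit`, `denoise`, `unlm-dwi`, `evaluate`, `uncertainty`,
`experiment`) is installed at `inst/cli/dtnlm`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "dtnlm", package = "dtnlm"))')" \
    experiment --seed 1 -o report.tsv
```

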