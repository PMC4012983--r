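# topofa

Topographic factor analysis (TFA) for functional brain images, in R.

fMRI datasets arrive as a series of 3-D images whose voxels are strongly
spatially correlated, because nearby voxels sample the same underlying
brain structures. TFA exploits that structure directly: it models each
image as a noisy weighted sum of `K` latent *sources*, where every source
is a spherical Gaussian radial basis function with a center `μ_k` and log
width `λ_k`,

    F[k, v] = exp(−‖r_v − μ_k‖² / exp(λ_k)),
    y[n, v] ~ N( Σ_k w[n, k] · F[k, v] , σ² ),

with independent Gaussian priors on the weights `w`, the centers, and the
log widths (all scales parameterized as log precisions). Fitting the model
to an image series yields interpretable structure that a general matrix
factorization cannot: each factor *is* a location and a size, the fitted
sources predict activation at voxels never seen during training, and the
covariance of the weight matrix across images is a compact `K × K`
brain-interaction network.

The package is for researchers who want to decompose an fMRI (or any
spatial value-by-location) dataset into a small set of localized sources,
choose `K` by held-out prediction, and test whether condition-specific
source networks are reliable.

Inference is black-box stochastic variational inference: a mean-field
Gaussian family, score-function gradient estimates with per-dimension
control variates, adaptive per-parameter learning rates, stochastic
subsampling of images and voxels, a deterministic "hotspot"
initialization from the folded mean image, and a closing full-data update
of the per-image weights. The methods vignette
(`vignettes/topographic-factor-analysis.Rmd`) documents the model, every
tunable, and the design decisions.

## Worked example

Simulate a dataset from the generative process with known ground truth,
fit it, and compare:

```r
library(topofa)

bundle <- generate_tfa_dataset(K = 3, N = 100, grid = make_grid(c(10, 10, 5)),
                               snr = 5, seed = 42)
fit <- tfa(bundle, K = 3,
           control = tfa_control(samples = 500, max_iter = 600, tol = 1e-6,
                                 window = 50, image_subsample = 50,
                                 voxel_subsample = 250, final_max_iter = 80),
           seed = 1)
summary(fit)
#> TFA fit: K = 3, 100 images x 500 voxels (680 iterations)
#>   smoothed ELBO -234120 | reconstruction RMSE 0.3368 | variance explained 83.2%
#> Sources (variational means):
#>  source      x     y      z log_width length_scale weight_sd
#>       1 7.4909 2.745 2.7392     1.811        2.473     1.846
#>       2 0.9407 4.469 0.8539     1.716        2.358     1.962
#>       3 4.1815 8.840 1.8186     2.250        3.080     1.882
```

The ground truth in this bundle is three sources at
(4.195, 8.846, 1.866), (7.476, 2.749, 2.715) and (0.940, 4.478, 0.867)
with log widths 2.266, 1.809 and 1.726 — each recovered (up to source
relabeling) to within a few hundredths of a voxel spacing, with widths to
two decimals. `variance explained 83.2%` is the model mean's share of the
activation variance at a signal-to-noise ratio of 5 — the rest is voxel
noise, which the model correctly declines to reconstruct.

Downstream, in a few lines:

```r
net <- weight_covariance(coef(fit, "weights"))   # K x K source network
#> Source network: 3 sources, 100 images
#>   interaction strengths: 3 pairs, |strength| range [0.262, 0.61]
threshold_network(net, 60)          # keep the strongest 40% for display
predict(fit, newcoords = rbind(c(2.5, 3.5, 1.5)))  # held-out locations
cv <- tfa_cross_validate(bundle$data, K_grid = c(1, 2, 3, 5))
select_k(cv)                        # argmax of held-out covariance prediction
```

`split_half_reliability()` tests whether condition-specific networks are
more similar across odd/even epoch splits than networks of different
conditions, with a row-shuffle permutation test;
`read_tfa_dataset()`/`save_tfa_results()` handle NIfTI + mask input and
TSV/NIfTI/JSON output; `inst/cli/topofa` exposes
`simulate`, `fit`, `reconstruct`, `cv` and `network` subcommands for shell
pipelines.

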