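---
title: "Topographic factor analysis: model, inference, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topographic factor analysis: model, inference, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topofa)
```

## The model

Topographic factor analysis (TFA) explains an fMRI series — an $N \times V$
matrix $Y$ of images by voxels, with a $V \times D$ table of voxel
coordinates $r_v$ — as a noisy weighted sum of $K$ latent spatial
*sources*. Each source $k$ is an isotropic Gaussian radial basis function
with center $\mu_k$ and log width $\lambda_k$:

$$F_{kv} = \exp\!\left(-\frac{\lVert r_v - \mu_k\rVert^2}{e^{\lambda_k}}\right),
\qquad
y_{nv} \sim N\!\Big(\sum_k w_{nk}\,F_{kv},\ \sigma^2\Big).$$

The per-image weights $w_{nk}$, the centers, and the log widths carry
independent Gaussian priors; all Gaussian scales in the package are
parameterized as **log precisions** (variance $= e^{-\rho}$), which keeps
every parameter unrestricted during stochastic optimization — the same
reason the width enters through its log. The joint density factorizes into
the likelihood times the three prior blocks, and `tfa_sample_generative()`
runs this process forward.

Because a source is a *function* of space, not a vector over the training
voxels, a fitted model can predict activation at coordinates never seen
during fitting (`predict(fit, newcoords = ...)`); the cross-validation
below leans on exactly this property. The $K \times K$ covariance of the
weight columns is read as a source-interaction network: positive entries
excitatory, negative inhibitory.

### Hyperparameters

`tfa_hyper()` derives defaults from the data: the center prior is centered
on the centroid of the voxel coordinates with per-dimension variance equal
to the coordinate variance, so a prior draw covers the imaged volume. The
voxel noise parameter defaults to 0.1 and is read as a **standard
deviation**; because the convention (sd, variance, or precision) matters
and is a frequent source of confusion, the constructor exposes
`noise_scale = c("sd", "variance", "precision")` rather than fixing one
silently. The weight prior is $N(0, 2^2)$ and the log-width prior
$N(1, 2^2)$ — broad on the scale of standardized BOLD data and of
voxel-unit coordinates, where $e^{(1 \pm 2)/2}$ spans RBF length scales of
roughly 0.6–4.5 voxel spacings. Broad priors leave the data in charge; the
defaults only set the scale.

## Variational inference

The posterior over weights, centers and widths is intractable, so the
package fits a fully factorized (mean-field) Gaussian family: one
(mean, log precision) pair per scalar latent variable, held in a
`tfa_state`. The evidence lower bound (ELBO) is maximized by stochastic
gradient ascent using **score-function ("black-box") gradients**: with
$f(\xi) = \log p(\xi, Y) - \log q(\xi)$ estimated from $M$ joint draws
$\xi_m \sim q$ (default $M = 500$),

$$\widehat{\nabla}_{\alpha_i} \mathrm{ELBO}
  = \frac{1}{M}\sum_m \nabla_{\alpha_i} \log q(\xi_m)\, f(\xi_m).$$

No model derivatives are needed; the Gaussian factor scores are analytic
($\partial_\mu = e^{\rho}(x-\mu)$,
$\partial_\rho = \tfrac12 - \tfrac12 e^{\rho}(x-\mu)^2$) and are verified
against finite differences in the test suite.

**Control variates.** The raw estimator is noisy. Since the score has
expectation zero under $q$, subtracting $a^* h$ with
$a^* = \widehat{\mathrm{Cov}}(hf, h)/\widehat{\mathrm{Var}}(h)$ per
parameter dimension shrinks the variance substantially. The coefficient
is estimated from the same batch, which carries an $O(1/M)$ bias —
negligible at $M = 500$ and, pleasantly, the estimator becomes *exactly*
zero-variance when $q$ reaches an exact (conjugate) posterior, because $f$
is then constant in the sample.

**Per-image objective for local parameters.** Inside the fitting loop the
gradient for image $n$'s weight parameters multiplies the score by only
image $n$'s part of $f$ (its likelihood rows, weight prior and entropy
terms). Terms not involving image $n$ have zero expected product with its
score and contribute only variance, so dropping them is a pure variance
reduction consistent with the mean-field factorization. The exported
`score_gradient()` keeps the plain shared-$f$ estimator, whose
unbiasedness the tests check against a quadrature oracle.

**Adaptive learning rates.** Each coordinate keeps an accumulator of
squared gradients; the step is
$\mathrm{rate\_scale} / (\delta + \sqrt{\mathrm{acc}})$ times the
gradient, clipped per coordinate at `max_step_size = 1`, with
$\delta = 10^{-6}$. The master numerator `rate_scale` (default 0.1) is
separate from the clip: on small-span synthetic grids the first few
updates are effectively sign steps of size `rate_scale`, and a numerator
of 1 would let the global parameters random-walk across a 10-voxel volume
before the accumulators tame it. The stationary jitter that remains is
removed by **tail averaging**: the reported centers and widths are the
average of the last `window` iterations (Polyak-style), after which the
weights are re-solved once by least squares.

**Subsampling.** Each outer iteration draws $N'$ images (default
$\min(100, N)$) and a contiguous block of $V'$ voxels (default
$\min(1000, V)$) — realized as the $V'$ voxels nearest a uniformly drawn
seed voxel, a rule that respects arbitrary masks. The likelihood is scaled
by $(N/N')(V/V')$ and the weight prior by $N/N'$, keeping the stochastic
gradient unbiased (property-tested over hundreds of subset draws). One
sample batch is drawn per iteration and reused for every parameter update
in that iteration.

**Weight re-solve.** After every update of the centers and widths, the
in-scope weight means are reset to the exact least-squares solution
$W = Y F^\top (F F^\top)^{-1}$. The regression solution is reliably at (or
extremely near) a local optimum of the objective in the weights, and
re-anchoring there after each global move keeps the loop stable.

**Convergence and divergence.** The stochastic ELBO trace is smoothed by a
25-iteration moving average; the loop stops when the smoothed value
changes by less than `tol` (relative, default $10^{-4}$; the
high-precision study conditions below use $10^{-6}$) across a window, or
at `max_iter`. A guard aborts with a diagnostic if the smoothed trace
falls more than `divergence` times the trace's spread below its best
value.

**The final update.** Image subsampling means some images may never be
drawn, so their weight factors still sit at initialization. `tfa()`
finishes by freezing the global parameters and re-running the stochastic
updates on all $N$ images and all $V$ voxels, weights only, with the basis
matrix evaluated once at the frozen center/width means. That choice makes
the $N$ subproblems independent and exactly conjugate — the global factors
are fixed in this phase anyway, and their post-fit dispersion is small —
and sufficient statistics ($FF^\top$, $FY^\top$) reduce each Monte Carlo
evaluation to $K \times K$ quadratic forms. On conjugate instances this
phase converges to the exact posterior mean and variance to machine
precision (the control-variate fixed point above).

## Initialization

The ELBO is riddled with local optima, so the starting point matters.

*Hotspot initialization* (default, deterministic): compute the mean image,
subtract its scalar mean, take absolute values ("fold"), then place
sources one at a time — each center at the current residual's peak voxel
(ties broken at the lowest voxel index), each width by a bounded 1-D
least-squares search over the log width with the amplitude fixed at the
peak's folded value. The fitted amplitude-scaled source image is
subtracted and the next source fit to the residual; the image is folded
only once, so over-explained regions go negative and repel later sources.
The width search interval is $[\log(0.25 s^2), \log(4\,\mathrm{span}^2)]$
($s$ = voxel spacing, span = bounding-box diagonal). Weights are then
initialized by least squares against the resulting basis matrix — using
all images, not just the mean.

*Random initialization*: one draw of all means from the prior. The test
suite checks that hotspot starts dominate random starts in initial ELBO on
seeded synthetic data.

Initial variational log precisions are configuration values
(`tfa_control`): weight sd 0.1, center sd half a voxel spacing, log-width
sd 0.25 by default — tight enough that early samples stay informative,
loose enough to explore.

## Synthetic data: what it emulates and what it does not

`generate_tfa_dataset()` draws sources, weights and noise exactly from the
model, then adds three controls that a recovery simulation needs:

- **SNR**: the noise variance is set so
  $\mathrm{var}(WF)/\sigma^2$ equals the requested signal-to-noise ratio
  (the model never fixes a noise level; this knob defines one).
- **Resolvable widths** (`width_range`, default 1–4 voxel spacings): the
  prior width draw is truncated so no ground-truth source is narrower than
  a voxel (invisible between grid points) or wider than the field of view
  (degenerate with the image mean).
- **Visible, separated centers** (`within_volume`, `separated`): centers
  are rejection-sampled into the coordinate bounding box and at pairwise
  distance at least twice the mean length scale. A source outside the
  imaged volume is unrecoverable in principle; *fitted* centers remain
  unconstrained, since a real fit may legitimately park a source outside
  the brain.

`generate_condition_dataset()` adds category structure for the network
analyses: condition $c$'s weights are drawn with covariance
$\Sigma_c = e^{-\rho_w} I + \text{effect\_size} \cdot u_c u_c^\top$ for a
condition-specific unit vector $u_c$ — at effect size 0 the conditions are
exchangeable, the exact null of the permutation test. Epochs are assigned
round-robin. `generate_hotspot_demo()` builds the classic 2-D, 25-source
image for exercising the initializer.

None of the generators emulate hemodynamics, temporal autocorrelation, or
spatially correlated noise: images are exchangeable and noise is i.i.d.
by construction, matching the model's own assumptions. Passing tests
therefore demonstrate correctness of the machinery under the model, not
robustness to the ways real fMRI violates it.

## Study conditions used by the tests and the acceptance script

Problem sizes were chosen once, as the scale at which each question is
scientifically meaningful on a desktop:

- **Parameter recovery**: $K=3$ well-separated sources on a
  $10 \times 10 \times 5$ grid ($V = 500$), $N = 100$ images, SNR 5,
  five replicates; fits use $M = 500$, up to 1000 iterations at
  `tol = 1e-6`, $N' = 50$, $V' = 250$. Success is assignment-matched mean
  center error below 1.5 voxel spacings with truth–estimate weight
  correlation above 0.9. A replicate can honestly fail when a source's
  *mean* weight is near zero — invisible to the mean-image initializer —
  and the fit settles in a duplicated-source optimum; the criterion asks
  for four of five.
- **Model selection**: $K_\text{true} = 3$ on an $8 \times 8$ grid,
  $N = 72$ (six folds of twelve), SNR 1, grid $\{1,2,3,5,8\}$. The noise
  level is the point of this experiment: with very clean data extra
  sources have nothing to overfit and the held-out covariance curve
  plateaus instead of peaking.
- **Networks**: six conditions, $K = 5$, 24 images per condition, six
  epochs. The row-shuffle null is discrete with $C!$ distinct
  permutations, so small $C$ caps the attainable p-value (at $C = 4$,
  $p \le 0.01$ is unreachable with +1 smoothing); six conditions keep the
  test able to resolve the 0.01 level while staying small.

## Numerical choices and degenerate inputs

- Coincident sources make $FF^\top$ singular; `solve_weights()` falls back
  to the pseudoinverse with a warning.
- A zero-variance score dimension leaves the control variate at
  $a^* = 0$ (no adjustment).
- Non-positive-definite condition covariances (possible only under exotic
  inputs) are repaired by eigenvalue flooring, with a warning.
- Pearson correlation is used wherever the analyses compare vectorized
  network strengths or covariance entries; covariance-matrix agreement
  uses all entries by default with an off-diagonal-only option.
- Peak ties in the initializer break at the lowest voxel index; K-selection
  ties break at the smallest K; a monotone-increasing CV curve returns the
  largest grid value with an overfitting warning.
- The permutation p-value uses +1 smoothing, so it is never smaller than
  $1/(\text{permutations}+1)$.

## Limitations

Sources are spherical; irregular activation patches are approximated by
several overlapping sources, trading spatial fidelity for
interpretability. Each participant is fit separately — there is no
hierarchical pooling. The score-function gradient, even with control
variates, is noisy enough that global parameters converge at the
stochastic-approximation rate, so very small problems benefit more from a
good initialization than from longer runs. Width estimates inherit a mild
upward bias from the hotspot fit against overlapping neighbors, which the
variational refinement then corrects only as far as the data demand.
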