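# ssmca — nonlinear spike-and-slab sparse coding

Sparse coding for occlusion-rich images. Standard sparse coding writes a
patch as a *linear* sum of dictionary elements with weakly sparse
coefficients; real image components, however, are either present or exactly
absent, and when opaque structures overlap the observed intensity is that of
the occluder, not the sum. `ssmca` implements a generative model built
around both observations:

$$y_d \sim \mathcal{N}\big(\max(0,\ \max_h s_h W_{dh}),\ \sigma^2\big),
\qquad s_h = b_h z_h,\quad b_h \sim \mathrm{Bern}(\pi),\quad
z_h \sim \mathcal{N}(\mu_{pr}, \sigma_{pr}^2)$$

Each latent coefficient $s_h$ carries a spike-and-slab prior — an exact
point mass at zero (component absent) plus a Gaussian intensity when present
— and components combine through a pixelwise maximum, a first-order model of
opaque occlusion. The dictionary $W$ ($D \times H$, nonnegative, columns
normalized to sum $D$), the noise level $\sigma$, the sparsity $\pi$ and the
slab $(\mu_{pr}, \sigma_{pr})$ are all learned.

Inference is the technically interesting part: the conditional posterior of
one latent given the rest is a *piecewise Gaussian with a point mass at
zero* — each pixel's likelihood switches from constant to Gaussian at a
transition point where that latent becomes the pixel's maximal cause. The
package builds this density exactly (sorted transition points, quadratic
segment algebra, truncated-Gaussian masses in log space) and samples it by
inverse-transform sampling, giving an *exact* Gibbs sampler for a strongly
multimodal posterior. Training is truncated EM: per patch, a cosine
similarity score preselects the $H'$ most relevant latents (plus optional
random extras), Gibbs sweeps over that subset supply posterior samples, and
closed-form M-step updates re-estimate every parameter. The hot loop is
compiled (Rcpp); per-datapoint counter-based RNG streams make runs
reproducible bit-for-bit and order-independent.

The package ships the surrounding laboratory as well: generators for the
bars benchmark and for opaque stroke-occlusion images with ground-truth
per-patch complexity labels, natural-image patch preprocessing
(pseudo-whitening, ON/OFF channel split, contrast normalization),
reconstruction and sparsity-versus-complexity evaluation, a
prior/posterior-consistency check, a frozen-slab control (`ssmca_fix`,
approximating a binary prior), and an adapter to scikit-learn's online
$\ell_1$ dictionary-learning baseline (requires a `python` interpreter with
scikit-learn; everything else is pure R/Rcpp).

## Worked example: recovering a generative model from bars data

The bars test draws patches from the model itself — ten single-pixel bars
(five horizontal, five vertical) on a 5×5 grid, two active per patch on
average, slab intensities $\mathcal{N}(2, 0.5^2)$, observation noise
$\sigma = 2$ — and asks the fit to recover every parameter and every bar.

```r
library(ssmca)

bars <- generate_bars(seed = 101)   # N = 2000 patches, D = 25, H = 10
fit  <- fit_ssmca(bars, H = 10, H_prime = 10, K = 30, n_iter = 30, seed = 1)
fit$params
#> ssmca model parameters: D = 25 pixels, H = 10 latents
#>   sigma = 1.991, pi = 0.2029 (pi*H = 2.03), mu_pr = 2.062, sigma_pr = 0.4941

# every generating bar matched by a learned column?
ncc <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
M <- outer(1:10, 1:10, Vectorize(function(i, j) ncc(bars$W_true[, i], fit$params$W[, j])))
round(apply(M, 1, max), 3)
#>  [1] 1 1 1 1 1 1 1 1 1 1
```

The generating values were $\sigma = 2$, $\pi H = 2$, $\mu_{pr} = 2$,
$\sigma_{pr} = 0.5$: the fit recovers the noise level within half a
percent, the sparsity within 0.03 components, and every bar at a normalized
cross-correlation of 1.000. EM on this landscape does have local optima
(roughly one seed in four leaves two bars entangled, visibly ~6 nats worse
in joint log-likelihood); running a few restarts and keeping the
highest-likelihood fit, as the acceptance script does, makes recovery
routine.

On the stroke-occlusion data (opaque strokes painted over each other, cut
into 9×9 windows with known per-window stroke counts `k`), the model's
reconstruction sparsity tracks the true complexity — patches with more
occluding strokes use proportionally more components, noise-only windows
use none — while the frozen-slab control reconstructs strictly worse; see
`sparsity_vs_complexity()` and the methods vignette
(`vignettes/nonlinear-spike-and-slab-sparse-coding.Rmd`).

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/ssmca", package="ssmca"))') \
    generate --preset fig_bars --seed 1 --out run1
```

with subcommands `generate`, `fit` (`--resume`), `evaluate` and `baseline`,
YAML configs and named presets; datasets and checkpoints are plain-text
containers (CSV + JSON).

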