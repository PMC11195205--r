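---
title: "Semi-synthetic training for point-scanning image restoration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-synthetic training for point-scanning image restoration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Point-scanning microscopes (confocal, scanning EM) acquire one pixel at a
time, so resolution, signal-to-noise ratio and acquisition speed trade off
directly through the pixel dwell time. A restoration model that maps fast,
undersampled, noisy acquisitions to the quality of slow, well-sampled ones
relaxes this trade-off — but training such a model ordinarily requires
perfectly aligned pairs of low- and high-quality acquisitions, which are
difficult to collect.

`pointsr` side-steps the pairing requirement by *crappification*: real
low-quality images are emulated from high-quality ones by downsampling
followed by noise injection, so that only high-quality acquisitions are
needed. The package covers the full loop — degradation model, noise
calibration against real pairs, leakage-safe tiled datasets, residual U-Net
training with an MS-SSIM + L1 loss, tiled whole-image prediction, and
benchmarking against a bilinear-upscaling control.

## The degradation model and why order matters

A crappifier is `noise(downsample(x))`, strictly in that order. Downsampling
is area (box) averaging over `scale × scale` blocks, modelling detector
binning. The supported noise families are:

* **poisson** — shot noise. A pixel `x ∈ [0,1]` becomes
  `Poisson(x·gain/s)·s/gain` with `s = max(intensity, ε)`. `gain` is the
  expected photon count of a full-scale pixel; `intensity` coarsens the
  photon statistics without changing the mean. The variance of a pixel is
  `x·intensity/gain`.
* **additive_gaussian** — read noise, `x + N(0, intensity)`; `intensity` is a
  standard deviation in normalized intensity units.
* **poisson_gaussian** — both stages in sequence.

The order is the crux: were noise injected *before* downsampling, each output
pixel would average `scale²` independent noise values, shrinking the noise
variance by that factor. A crappifier built that way produces training inputs
systematically cleaner than real undersampled acquisitions, and the trained
model under-corrects on real data. `apply_noise` after `downsample` makes the
variance ratio between the two orders exactly `scale²` for value-dependent
noise; the test suite and the acceptance script verify the ratio empirically
(`≈ 16` at scale 4 over ≥10⁵ pixels).

During training the noise intensity is drawn fresh from a configurable
uniform range on *every* item access, and items are re-crappified every
epoch. Each epoch therefore sees a statistically independent degradation of
every tile, which multiplies the effective dataset size and widens the input
quality range the model tolerates. Drawing per call (rather than per epoch or
per image) is the finest natural granularity; it costs nothing and maximizes
augmentation diversity.

## Calibrating the crappifier against real pairs

When a few real high/low pairs exist, the crappifier can be fitted instead of
guessed. The *noise profile* of a pair is `lr_true − downsample(hr, scale)`,
an unclipped signed residual array whose value distribution characterizes the
acquisition noise. The fit minimizes the mean (over pairs) 1-Wasserstein
distance between the value distributions of the measured profile and of the
profile produced by a candidate crappifier on the same clean image.

Choices made here, and why:

* **1-Wasserstein on pooled values.** It is a proper metric on empirical
  distributions, is robust to shifted or rescaled noise laws, and has an
  exact sorted-sample estimator (`mean |sort(a) − sort(b)|` for equal sizes,
  CDF integration otherwise). Residuals are subsampled to ≤10⁵ values per
  evaluation; the estimator is stable well below that.
* **Gaussian-process Bayesian optimization.** The objective is a
  Monte-Carlo quantity, ~0.1–1 s per evaluation, with a 1–3 dimensional
  smooth surface — the textbook case for a GP surrogate. The surrogate uses
  a Matérn-5/2 kernel with marginal-likelihood hyperparameters,
  expected-improvement acquisition maximized over a random candidate cloud
  plus jitter around the incumbent, and a 10-point Latin-hypercube initial
  design. Each candidate is evaluated with one shared noise seed so the
  surface is quasi-deterministic, which GP optimization assumes.
* **Budget.** 40 evaluations recover an additive-Gaussian σ within a few
  percent on four 256×256 pairs; the suite requires ≤15% median error over
  σ ∈ {0.05, 0.1, 0.2} and 5 seeds.

## Tiled datasets and the leakage-safe split

Large acquisitions are handled as square tiles on a regular grid
(`stride = tile_size − overlap`; 0-based positions, half-open pixel boxes).
Non-spatial axes (time, depth, channel) are flattened into *frames* of the
same tile position. Frames of one tile are near-identical views, so a random
split by frame would leak effectively-duplicate data into validation; the
split therefore shuffles distinct `(image, row, col)` tile keys and every
frame follows its tile. Asymmetric input/output dimensionality (several
frames in, one frame out) is expressed by a single `frame_window` parameter
whose window is centred on the target frame and clamped at the ends.

Boundary policy defaults differ by purpose: `drop` for training (targets must
contain no padding artifacts) and `pad_reflect` for prediction (full
coverage). Stitching places tiles back at their origins and averages overlaps
with equal weights — the simplest scheme with an exact round-trip property
(`stitch(tile(x)) == x` to 1e-6 on un-padded regions, all overlaps), which
the suite checks. Feathered blending is deliberately deferred.

## Model and training

The restoration model is a residual U-Net: pre-activation residual blocks at
every level, stride-2 convolution downsampling with channel doubling,
nearest-neighbour + convolution upsampling with skip concatenation, and a
sub-pixel (pixel-shuffle) head when `scale > 1`. A global skip adds the
bilinearly upscaled input to the output, so the network learns a residual
over plain interpolation — with zero weights the model *is* the bilinear
control, and training can only improve on it. `scale = 1` gives a pure
denoiser. The named architecture fixes neither depth nor width; the defaults
here (`base_channels = 16`, `depth = 3`) are sized for CPU-scale
experiments, and parameter count is a pure function of the spec and seed.

The forward and backward passes are implemented in the package (im2col +
BLAS convolution primitives in compiled code, analytic MS-SSIM gradient in
R) and are verified against finite differences to ~1e-8 in the test suite.
Training is plain minibatch Adam (default learning rate 5e-4; the small
acceptance task uses 2e-3), fully seeded and reproducible on one device; the
best-validation checkpoint is retained.

The loss is `α·(1 − MS-SSIM) + (1 − α)·mean|pred − target|` with `α = 0.84`
following the mixed-loss literature; the Gaussian-weighted L1 of that
literature is simplified to plain L1 (documented deviation — the weighting
changes little at these tile sizes). MS-SSIM uses the standard 11-pixel
Gaussian window (σ 1.5), C1/C2 constants, valid-window statistics, 2×2 area
pooling between levels, and the standard five-level weights renormalized
when fewer levels fit the tile (`levels = ⌊log2(extent/11)⌋ + 1`, e.g. 3
levels at 64 px). Contrast terms are floored at 1e-6 before the geometric
mean so small negative covariances cannot produce NaN. PSNR is capped at
100 dB for identical images so aggregates stay finite. All three metrics
match independent reference implementations to better than 1e-9 on seeded
random pairs; the suite asserts 1e-4.

## Synthetic study conditions

The synthetic generator renders Gaussian puncta (amplitude 0.4–0.9, width
1–2 px, minimum separation enforced) and random-walk filaments on a flat
background (default 0.1), blurred by a Gaussian PSF (σ 1.5 px) — a stand-in
for fluorescence/EM texture diversity, with no claim of optical realism. The
degradation used across the end-to-end tests is Poisson noise with
`gain = 100` and intensity drawn from U(0.5, 1.5): at typical structure
intensities this gives per-pixel noise sd ≈ 0.05–0.1, i.e. strongly
shot-noise-limited acquisitions of the kind undersampled point-scanning
produces; the bilinear control then scores ~32–33 dB PSNR / 0.8 SSIM,
leaving real headroom for restoration. The acceptance-scale task trains on
fifty 48-px HR tiles from four 256×256 specimens for ~500 optimizer steps
(a twelve-tile held-out set selects the best checkpoint, since Adam at this
step size can wander late in training) and
benchmarks on ten held-out 128×128 pairs; a run takes a few minutes on one
CPU and the trained model exceeds the control by roughly 1.5–3 dB PSNR and
~0.15 SSIM depending on the seed.

What passing these tests does *not* show: performance on real microscopy
(optics, spatially correlated noise, scan artifacts and drift are all absent
from the generator), or parity with any published full-scale model. They do
show that every mechanism — degradation order, calibration, split hygiene,
loss, training loop, tiled inference, scoring — behaves as specified.

## Numerical choices and degenerate inputs

* Canonical intensity range is float [0,1] (divide by the dtype maximum on
  read); crappifier intensities are therefore comparable across 8- and
  16-bit sources. Round trips are exact to one quantization step.
* Unknown TIFF page structure defaults to a single leading `T` axis;
  axis labels are restricted to {T, Z, C, Y, X} with Y, X last.
* Poisson rates use `max(intensity, 1e-6)` so intensity 0 degenerates to the
  noise-free limit instead of dividing by zero.
* Post-noise clipping to [0,1] is on by default (canonical range) and can be
  disabled for noise-statistics work, where clipping would bias variances.
* Non-divisible extents raise errors rather than silently cropping
  (`crop = TRUE` opts in); tile grids that fit nowhere raise an
  empty-result error rather than returning nothing.
* The GP fit floors the kernel with a small nugget and falls back to a large
  penalty on Cholesky failure; candidates are clamped to the unit cube.

## Known limitations

Single-device CPU training only; square tiles; uniform overlap blending; no
spatially varying noise fields or joint PSF fitting; no streaming datasets;
proprietary microscope formats are out of scope (convert to TIFF first).
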