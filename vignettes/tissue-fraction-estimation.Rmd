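---
title: "Estimating tumor-fraction areas in PET: model, simulation framework, and design choices"
author: "tfaseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tumor-fraction areas in PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Tumor segmentation in oncological PET is limited by partial-volume effects
(PVEs): the scanner's finite resolution blurs tumor boundaries, and the
finite pixel size means boundary pixels contain a *mixture* of tumor and
normal tissue — the tissue-fraction effect (TFE). A classifier that assigns
each pixel wholly to one class cannot represent that mixture. `tfaseg`
instead poses segmentation as *estimation*: for each pixel $m$ of a 2D PET
slice, estimate the tumor-fraction area (TFA)

$$a_m \;=\; \frac{1}{A}\int \mathrm{d}^2 r\; s(\mathbf r)\,\phi_m(\mathbf r)
\;\in\; [0,1],$$

where $s(\mathbf r)$ is the indicator of tumor uptake, $\phi_m$ the pixel
indicator, and $A$ the pixel area. The tumor cross-section area is the L1
norm of the TFA map times $A$.

## The estimator and why BCE training yields the posterior mean

Estimating $\mathbf a$ from the reconstructed image $\hat{\mathbf f}$ is
ill-posed (projection and reconstruction have null spaces), so the package
takes a Bayesian view. The estimator $\hat{\mathbf a}(\hat{\mathbf f})$ is
trained by minimizing the aggregate binary cross-entropy cost

$$\ell(\mathbf a, \hat{\mathbf a}) = \sum_m
  \big[-a_m \log \hat a_m - (1-a_m)\log(1-\hat a_m)\big]$$

averaged over the joint distribution of true maps and noisy images. Setting
the functional derivative of the population cost to zero pixel-wise gives
$-a_m/\hat a_m + (1-a_m)/(1-\hat a_m) = 0$ in posterior expectation, whose
solution is

$$\hat a_m^\* = \int \mathrm d a_m\; \mathrm{pr}(a_m \mid \hat{\mathbf f})\, a_m,$$

the **posterior mean** — the estimator with minimum ensemble mean squared
error (EMSE), and unbiased in the Bayesian (joint-average) sense. The BCE
form is used rather than squared error because it bakes the $[0,1]$
constraint into the cost.

Because the full posterior is intractable, the estimator is a convolutional
encoder–decoder trained on simulated (image, TFA map) pairs: a contracting
path that halves the spatial dimensions per level while doubling channels,
an expansive path that restores them, skip connections added element-wise,
and a final $1\times1$ convolution squashed through a logistic so outputs
lie strictly in $(0,1)$ (required for the cost to stay finite; log
arguments are additionally floored at `clampEps = 1e-7` when the cost is
reported). Optimization is Adam on minibatches (per-image pixel sum, mean
over the minibatch — invariant to batch size).

Two implementation choices depart from a textbook U-net, both deliberate:

* **No batch normalization.** At the scales used here the plain conv+ReLU
  network (He-normal initialization) trains stably, the analytic
  backpropagation can be verified against finite differences to $10^{-5}$
  relative error (and is, in the test suite), and training is strictly
  deterministic given the seed.
* **Average pooling / nearest-neighbor upsampling** rather than strided or
  transposed convolutions: linear, artifact-free resamplers that keep the
  parameter count small.

The network is implemented from first principles in C++ (im2col + GEMM);
there is no deep-learning framework behind it.

### Verifying the theory: the scalar toy model

The posterior-mean property is checked empirically on an observation model
whose posterior *is* tractable: each pixel draws $v \sim \mathrm{U}[0,1]$
i.i.d., observed as $v + \mathcal N(0, \sigma^2)$ with $\sigma = 0.1$.
`posteriorMeanOracle()` computes $E[v \mid \text{obs}]$ by trapezoid
quadrature (2048 nodes; refinement-stable to $<10^{-6}$, and checked
against self-normalized importance-sampling Monte Carlo). The package's
verification protocol trains the standard network (depth 2, 8 base
channels, $16\times16$ inputs) on 600 toy images for 50 epochs at learning
rate $2\times10^{-3}$ followed by 25 refinement epochs at $3\times10^{-4}$
(the two-stage schedule removes the last bit of calibration bias that a
single constant rate leaves behind). The trained output tracks the oracle
with mean absolute deviation well under 0.03, its joint-average bias is
statistically indistinguishable from zero, and its MSE beats the plug-in
(clamped identity) and every constant estimator — the defining property of
the posterior mean.

## The simulation framework

Ground truth requires knowing $s(\mathbf r)$ at effectively continuous
resolution, so evaluation is simulation-based. Each slice is built as
follows (`samplePhantom`, `simulateSlice`):

1. **Tumor support** at grid ratio $R$ per axis (default 32 relative to the
   PET grid, i.e. 0.127 mm at 4.07 mm pixels; the desk-scale studies and
   tests use $R = 8$ and $R = 4$): a random number of Gaussian lumps
   (Poisson count, clustered centers, uniform widths and amplitudes) is
   summed and thresholded — the threshold chosen by rank selection so the
   largest connected component hits a target area drawn uniformly from
   1–9 cm² — giving connected, irregular, realistic shapes. Draws outside
   the area range are rejected.
2. **Tumor activity**: a positive base plus nonnegative-clipped lumpy
   texture on the support, rescaled so the mean uptake equals TBR × the
   background mean, TBR ~ U(2, 8). Activity is strictly positive exactly
   on the support, so the support recovered from activity is exact.
3. **Background** (a synthetic stand-in for clinical background templates,
   which are not distributable): an elliptical body at unit uptake with
   additive lumpy heterogeneity and a low-uptake lung ellipse (×0.25)
   inside which the tumor is placed — emulating the high-contrast lung
   presentation of the clinical population.
4. **Imaging**: the tumor is blurred at its native high resolution
   (pixel-integrated Gaussian kernel, FWHM 5 mm) and integrated onto the
   PET grid; the background follows the PET-resolution path; both are
   projected by a precomputed sparse pixel-driven parallel-beam projector
   (84 angles over 180° for the 64×64 studies) and the sinograms are
   *added*, so reconstruction acts on their sum and the noise texture is
   shared. Counts are scaled to $5\times10^5$ expected events per slice
   and Poisson noise applied.
5. **Reconstruction**: OSEM, 21 angle-interleaved subsets × 2 iterations,
   uniform positive initialization. The reconstruction operator uses the
   geometric projector only — no resolution modeling — so the
   reconstructed image retains the system blur. This is what makes the
   PVE-sensitivity study meaningful.

The exact TFA ground truth is then `computeTFA`: integer sub-pixel counts
over each PET pixel divided by $R^2$ — exact by construction, and tested
against a brute-force per-pixel loop. The same counting operation serves
user-supplied high-resolution manual masks (nested, aligned grids; the
clinical convention of mask pixels at 1/8 the PET pixel size flows through
unchanged). Misaligned mask grids requiring polygon clipping are out of
scope.

### What the generator does *not* emulate

Attenuation, scatter, randoms, detector normalization and deadtime are
absent (they are applied as corrections in clinical protocols), as are 3D
effects, respiratory motion, and anatomical atlases. Tumor shape/size/TBR
distributions are parametric stand-ins for the (unpublished) clinical
distributions. Passing tests therefore demonstrate correctness of the
method and its advantage over classification *under this generative
model*, not clinical-grade performance.

## Study sizes and numerical choices

The headline study (`runScaledStudy`) uses 64×64 slices, 4.07 mm pixels,
5 mm FWHM — preserving the clinical FWHM-to-pixel ratio — with 500
training and 100 held-out slices, grid ratio 8, and a depth-3 network with
8 base channels trained 35 epochs (Adam, learning rate $10^{-3}$, batch
10). These sizes were chosen as the package's reference configuration so
that a complete run finishes in minutes on a single CPU while reproducing
the reference accuracy levels (mean fuzzy DSC ≈ 0.9, JSC ≈ 0.83,
normalized area EMSE ≲ 0.02); the network is smaller than the
configurable default (depth 3, 32 channels) for the same reason.
Five-fold cross-validation over a (learning rate × architecture) grid is
available via `crossValidate()` for users who wish to re-tune.

Other numerical choices:

* **Projector**: pixel-driven with linear bin interpolation, bin size =
  pixel size, bins = image dimension; the adjoint is the exact matrix
  transpose (tested to $10^{-6}$ relative). Activity is kept inside the
  inscribed ellipse of the field of view so detector truncation never
  clips the object.
* **OSEM guards**: bins with zero predicted counts contribute zero ratio;
  pixels with zero subset sensitivity stay zero. With one subset the
  update is exactly MLEM and the Poisson likelihood is non-decreasing
  (tested).
* **Degenerate metrics**: DSC and JSC are defined as 1 when both maps are
  identically zero; isocontour levels 0 and 1 are evaluated at
  $\pm 10^{-6}$ so they bound the support and the fully-tumor region; a
  constant map has no level crossings and returns empty contour sets.
* **Confidence intervals** are Student-t over per-slice values, and paired
  comparisons use the two-sided paired t-test; the per-slice unit is
  recorded in the report.
* **PVE-affected masks**: the boxcar width defaults to the smallest odd
  pixel count spanning the FWHM. Mass conservation makes the *continuous*
  blurred map's area ratio identically 1, so the binary convention
  thresholds at 40% of the blurred map's maximum (mirroring SUV-max
  practice); its spill-out then overestimates area, most strongly below
  2 cm² — the behavior the sensitivity study quantifies. A 0.5 threshold
  was considered and rejected: blurring a convex object pulls the 0.5
  level set inward, *under*estimating small tumors, contrary to how
  resolution loss manifests in measured PET areas.
* **Determinism**: all stochastic steps draw from R's RNG under explicit
  seeds (the C++ trainer receives its shuffling orders from R), so
  phantoms, training and reports are bit-reproducible; multi-threaded
  BLAS nondeterminism is outside the contract.

## Known limitations

2D slices only; single connected tumor per slice; no scanner-specific
physics beyond pixel size / FWHM / count level (alternative scanner
configurations are expressed as config presets); the classification
baseline shares the estimator's architecture, so the comparison isolates
the training target (binary vs fractional), not architectural choices.
Published third-party segmentation algorithms (active contours, MRF-GMM,
fuzzy C-means variants) are not reimplemented.
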