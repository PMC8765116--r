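# tfaseg — Bayesian tissue-fraction estimation for PET tumor segmentation

Tumor segmentation in oncological PET is degraded by partial-volume
effects: the scanner's ~5 mm resolution blurs boundaries, and at ~4 mm
pixels many pixels straddle the tumor edge and contain a *mixture* of
tumor and normal tissue (the tissue-fraction effect). Methods that label
each pixel as wholly tumor or wholly background cannot represent that
mixture, and their areas are systematically wrong for small tumors.

`tfaseg` poses the problem as estimation instead of classification. For
each pixel *m* it estimates the **tumor-fraction area**

> a_m = (1/A) ∫ s(r) φ_m(r) d²r ∈ [0, 1],

the fraction of the pixel occupied by tumor (s = tumor support indicator,
φ_m = pixel indicator, A = pixel area). A convolutional encoder–decoder
with element-wise-addition skip connections is trained by minimizing the
aggregate binary cross-entropy cost

> ℓ(a, â) = Σ_m [ −a_m log â_m − (1 − a_m) log(1 − â_m) ],

whose population minimizer is the **posterior mean** E[a_m | image] — the
estimator with minimum ensemble mean squared error, unbiased in the
Bayesian sense. The package verifies this property numerically against a
quadrature oracle on a tractable toy model.

For whom: researchers in PET quantification / medical image analysis who
need a fully reproducible, ground-truth-equipped test bed for
estimation-based segmentation — and a reference implementation of the
method itself (the network and its training loop are implemented from
first principles in C++; no deep-learning framework is required).

The package provides, as S4 classes and functions:

* a clinically structured 2D simulation framework — lumpy-model tumors at
  high sub-pixel resolution with heterogeneous activity, synthetic
  body/lung backgrounds, pixel-integrated Gaussian system blur,
  sparse-matrix parallel-beam projection, Poisson noise, OSEM
  reconstruction (21 subsets × 2 iterations);
* exact TFA ground truth by sub-pixel counting (`computeTFA`), for
  simulated supports and for user-supplied high-resolution manual masks;
* the estimator (`trainEstimator`, `predictTFA`) with deterministic
  seeded training, checkpointing, and five-fold cross-validation;
* fuzzy segmentation metrics (min/max confusion cardinalities, Dice and
  Jaccard on continuous maps), pixel-wise and normalized-area EMSE,
  ensemble-bias maps, isocontour topographic maps;
* baselines and sensitivity machinery: 40% SUV-max thresholding, a
  classification-trained network, PVE-affected masks, and area-binned
  reporting (`areaRatioStudy`).

## Worked example

The headline experiment — simulate 600 slices (64×64, 4.07 mm pixels,
5 mm FWHM), train on 500, evaluate on 100 held-out slices:

```r
library(tfaseg)
res <- runScaledStudy(seed = 11, nTrain = 500, nTest = 100)
res$report
```

```
EvalReport
  pixel-wise EMSE:      1.299
  normalized area EMSE: 0.009247
  DSC: 0.920 (95% CI 0.915, 0.925)
  JSC: 0.853 (95% CI 0.845, 0.861)
  bias map range: [-0.0219, 0.029]
  samples: 100 tumors x 1 realizations
  per-area-bin summary:
 binLow binHigh  n ratioMean ratioCiLow ratioCiHigh   dscMean   jscMean
      0       2 14 0.9841145  0.9001172    1.068112 0.9049218 0.8272101
      2       4 23 0.9667342  0.9264560    1.007012 0.9110195 0.8373425
      4       6 30 0.9928573  0.9630986    1.022616 0.9258437 0.8625504
      6       8 23 1.0214151  0.9884541    1.054376 0.9329571 0.8749597
      8      10 10 0.9694675  0.8954692    1.043466 0.9142479 0.8432095
```

Reading the report: the estimator's fuzzy Dice overlap with the exact
ground-truth TFA maps averages 0.92; its tumor-area estimates err by well
under 10% in mean square (normalized area EMSE 0.009); every pixel of the
ensemble-average bias map lies within ±0.03, the empirical signature of a
Bayesian-unbiased (posterior-mean) estimator; and the area ratio Â/A stays
within a few percent of unity in every size bin — including tumors under
2 cm², where binary PVE-affected masks overestimate area substantially
(`pveBinaryMask` + `areaRatioStudy` quantify this).

Smaller building blocks:

```r
sys <- systemModel(64, pixelSizeMm = 4.07, fwhmMm = 5, nAngles = 84)
ph  <- samplePhantom(tumorConfig(), lumpyParams(6, c(15, 40), c(0.2, 0.6)),
                     64, 4.07)          # high-res tumor + background
img <- simulateSlice(ph, sys)           # project -> noise -> OSEM
tfa <- computeTFA(ph)                   # exact ground truth
```

A thin CLI over these functions ships in `inst/scripts/tfaseg.R`
(`simulate`, `train`, `predict`, `evaluate`, `run-experiment`).

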