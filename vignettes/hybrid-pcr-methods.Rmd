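---
title: "Methods: hybrid MRI-radiomics prediction of pathologic complete response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid MRI-radiomics prediction of pathologic complete response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridpCR)
```

## The problem

Patients with locally advanced cervical cancer receive neoadjuvant
chemoradiotherapy (nCRT) before radical surgery. Whether a patient reaches
pathologic complete response (pCR) — no residual tumor in the surgical
specimen — is the reference read-out of radiosensitivity, but it is only
known after surgery. The goal of this package is a classifier that predicts
pCR *before* treatment from two pre-treatment sources: the T2-weighted MRI
tumor volume (with its contoured gross tumor volume, GTV) and five routine
clinical parameters (age, FIGO stage, pathological type, serum SCC antigen
band, lymph-node status).

The model is a *hybrid*: it combines three feature families that describe
the tumor at different levels of abstraction,

1. **domain-specific radiomics features** — hand-defined shape,
   first-order-intensity and gray-level-matrix texture statistics of the 3D
   GTV, implemented here from their formulas;
2. **abstract features** — channel-wise global-average-pooled activations
   tapped after each of the five stages of a VGG-style convolutional
   backbone applied to the largest tumor slice; and
3. **encoded clinical parameters**;

and classifies with an ensemble of standard base learners whose votes are
weighted by their validation accuracy.

## Pipeline stages and their parameters

### Preprocessing

Volumes are resampled to a common grid of 0.5 x 0.5 x 3 mm (trilinear for
images, nearest-neighbour for label masks; the through-plane axis is the
third array axis). The resampled grid size per axis is
`round(old_size * old_spacing / new_spacing)` with half rounded away from
zero. Intensities are then min-max normalised to [0, 1] over the whole
volume; a constant volume maps to zeros to avoid 0/0. For the
convolutional branch, the axial slice with the largest ROI area is
selected (ties go to the lowest index, for determinism), cropped to the
tight mask bounding box (configurable margin, default 0), resized
bilinearly to 224 x 224 and replicated to three identical channels.

### Domain-specific features

The catalogue (`inst/extdata/feature_catalogue.json`) fixes names, family
membership and order: 14 shape + 18 first-order + 24 GLCM + 16 GLRLM +
16 GLSZM + 14 GLDM + 5 NGTDM = 107 features, the standard IBSI-style set.
The published analysis reports a 109-entry list whose exact appendix is
not available; the catalogue file therefore supports enabling/disabling
entries so any published configuration can be matched, and the two extra
entries are deliberately *not* guessed. Texture families are computed on an
equal-width discretisation of the ROI intensities (default 32 levels over
the ROI range — the images are already normalised to [0, 1]), with
distance-1 neighbourhoods, the 13 unique 3D directions averaged (not
merged) for GLCM/GLRLM, 26-connectivity for size zones, and a dependence
tolerance of 0 for GLDM (the dependence count includes the centre voxel,
so it ranges 1–27).

Degenerate inputs get documented sentinel values instead of NaN: on a
constant ROI, GLCM correlation and MCC are 1, IMC1/IMC2 0, first-order
skewness/kurtosis 0, NGTDM contrast/busyness/strength 0 and coarseness
1e6 when its denominator vanishes.

Surface area and mesh volume are measured on a marching-tetrahedra
triangulation of the 0.5 iso-surface of the mask occupancy field, after
smoothing the binary mask with a Gaussian of sigma = 1 voxel per axis.
Meshing raw binary data places every iso-crossing at an edge midpoint,
which produces a staircase surface whose area overestimates that of a
smooth object by a resolution-independent factor (sphericity of digitised
balls then plateaus near 0.79). With the smoothed occupancy the measured
area of digitised balls converges to the analytic sphere area and
sphericity rises monotonically toward 1 (0.994–0.995 at radii 5–16
voxels), at the cost of a small inward bias for objects only a few voxels
across. The smoothing sigma is in voxel units; with anisotropic spacing
this regularises the mesh rather than applying an isotropic physical
filter, which is acceptable because its purpose is purely geometric.

### Abstract features

The backbone follows the five-stage plan with channel widths
(64, 128, 256, 512, 512) and 3 x 3 same-padded convolutions + ReLU,
(2, 2, 4, 4, 4) convolutions per stage, and 2 x 2 max pooling after each
stage; a global average pooling tap after every pooling layer yields five
vectors whose concatenation has 64 + 128 + 256 + 512 + 512 = 1472
dimensions. ImageNet-pretrained weights are pluggable through a weights
file, but all shipped tests use He-scaled seeded random weights with zero
biases: the dimensional, pooling and selection contracts under test are
weight-independent, and this keeps the package self-contained. Convolution
is evaluated as nine shifted matrix products, so the forward pass runs on
BLAS (about 5 s per 224 x 224 slice for the full plan on one CPU).

An optional fine-tuning stage trains a logistic (softmax) head on the
concatenated pooled features by full-batch gradient descent, leaving the
convolutional body frozen. This is a deliberate desk-scale reduction of
backbone fine-tuning: it is cheap, exactly reproducible, and the pipeline
runs identically with the stage disabled (`epochs = 0` is the identity).

Feature selection uses the frequency-style chi-square score: each feature
is min-max scaled to [0, 1] (nonnegativity), then scored by
`sum_c (O_c - E_c)^2 / E_c` with `O_c` the feature's sum in class `c` and
`E_c` its expectation under class independence. The top 90 of the 1472
pooled features are kept (ties to the lower index). Scaling and selection
are fitted inside each training fold only — never on test data — matching
the leakage-free protocol the study emphasises. Whether the original
analysis selected per-fold or once globally is not stated; per-fold is the
conservative choice and is what this package does.

### Clinical encoding

Each record contributes exactly 5 numeric values, so the domain vector has
catalogue_size + 5 entries (109 + 5 = 114 in the published configuration,
107 + 5 = 112 with the default catalogue) and the selected abstract vector
90 + 5 = 95: age scaled over [25, 65] years; FIGO stage IB/IIA–IIB/
IIIA–IIIC1 as 0/1/2; pathological type squamous/adeno/other as 0/1/2; SCC
band <1.5 / 1.5–5 / >5 ng/mL as 0/1/2 with "unclear" an explicit fourth
code 3 (not imputed); lymph node negative/positive as 0/1. Age enters as a
scaled continuous value because the 5-dimension arithmetic leaves no room
for one-hot expansion.

Cohort comparisons (`chi_square_independence`, `pipe_stats`) use plain
Pearson chi-square *without* continuity correction; with Yates' correction
the published tumor-diameter table would give p ≈ 0.94 instead of the
printed 0.787, so the uncorrected form is the one that reproduces the
published table. Three of the printed rows (tumor diameter 0.787,
lymph node 0.068, radiotherapy technology 0.886; also the SCC band,
0.117) reproduce to three decimals; the stage and pathological-type rows
do not reproduce under any plain Pearson test of the printed counts
(0.828 vs 0.846 and 0.167 vs 0.116) and are therefore reported but not
asserted.

### The ensemble

Four base classifiers — ridge-penalised logistic regression, an RBF
support-vector machine, k-nearest neighbours, Gaussian naive Bayes — are
each trained on the domain vector and on the abstract vector, giving the
8-member ensemble. Members output class-probability vectors
`h_i = (h_i1, h_i2)` over (non-pCR, pCR); the ensemble predicts

$$H(x) = \arg\max_j \sum_{i=1}^{8} w_i\, h_{ij}(x), \qquad
  w_i = \frac{e^{x_i}}{\sum_j e^{x_j}}, \qquad
  x_i = \mathrm{logit}(p_i),$$

where `p_i` is member *i*'s accuracy on validation data. At
cross-validation time no external validation set exists, so `p_i` comes
from an inner stratified hold-out of 20% of the training fold; members are
refit on the full training fold after `p_i` is recorded, preserving
test-fold purity. Accuracies are clipped to `[1e-6, 1 - 1e-6]` so logits
stay finite; exact argmax ties resolve to non-pCR; the class order
(non-pCR, pCR) is fixed everywhere.

Base-learner settings are deliberately plain and live in
`hybrid_control()`: ridge penalty `lambda = 0.01` (the small-n,
p > n regime makes a weak ridge necessary for the logistic member),
SVM cost 1 with `gamma = 1/p`, k = 5 neighbours, Gaussian naive Bayes
with no tuning. Features are standardised (training-fold mean/sd) before
every member; zero-variance columns are dropped. SVM probabilities come
from Platt scaling of the decision values, fitted by logistic regression
on the training fold: this keeps the member exactly reproducible, whereas
the widely used internal cross-validated calibration draws from a
non-seedable random stream. KNN probabilities are the fraction of pCR
labels among the k nearest training points (stable ordering breaks
distance ties).

### Evaluation

`run_repeated_cv()` performs stratified 5-fold cross-validation repeated
20 times by default (tests and examples use fewer repeats; the acceptance
checks run 5 repeats at n = 138, which completes in well under a minute).
Stratification balances per-class counts to within 1 across folds and
fold totals greedily, so the 74/64 cohort yields test folds of sizes
28, 28, 28, 27, 27. Fold assignments derive only from the base seed and
repeat index. Metrics are AUC (trapezoidal area under the empirical ROC,
identical to the tie-corrected rank statistic) from the ensemble pCR
probability, and ACC/TPR/TNR/precision from the argmax decision of the
vote (not from a 0.5 threshold; the two coincide only when the weighted
vote is a proper probability). Mean ± sd is reported at the fold level
(all `n_folds * n_repeats` values) with the repeat-level sd exported
alongside, since the published tables do not state their grain. ROC curves
are vertically averaged on a fixed 101-point false-positive-rate grid with
linear interpolation, preserving the (0,0) and (1,1) endpoints.

The six feature-combination variants mirror the published comparison:
clinical only (A), domain (B), domain + clinical (C), abstract after
selection (D), abstract + clinical (E), and the full hybrid (F). The
single-classifier ablations train each base type alone on the
concatenation of domain, clinical and the per-fold-selected abstract
block (204 dimensions with the default catalogue — one clinical copy;
the published text is ambiguous about whether clinical parameters were
concatenated once or twice, and a single copy avoids duplicated
features).

## The synthetic cohort

No imaging data are deposited with the study, so the package generates
phantoms that emulate the *study conditions* rather than MRI physics:

* **cohort**: 138 patients, 74 pCR / 64 non-pCR, mirroring the published
  cohort split;
* **imaging**: an ellipsoidal GTV (default semi-axes 15 x 12 x 9 mm on a
  64 x 64 x 16 grid of 1 x 1 x 3 mm voxels, coarser than the analysis grid
  so resampling is exercised) filled with a smoothed Gaussian random
  field. The pCR class differs by an intensity shift `delta_mean`
  (default 0.2 on the [0, 1] scale) and a texture correlation-length
  ratio `delta_texture` (default 1.5 on a 2 mm base length, realised as
  a larger smoothing scale — a texture-like signal, since texture is
  where the discriminative content of this kind of model lives). With
  both deltas 0 the classes are identically distributed by construction.
  Background is weak noise around 0.15; noise sd defaults to 0.05,
  texture sd to 0.08 — values chosen once as plausible for normalised
  T2-weighted tumor interiors;
* **clinical tables**: categorical marginals matching the published
  per-class proportions up to rounding, ages from a clipped discretised
  normal centred at the published medians (48 / 47 years) in 25–65;
* **feature matrices**: a fast path for classifier experiments —
  class-conditional Gaussians of the final vector widths (114 / 95) with
  20% informative columns shifted by `effect` standard deviations.

What passing tests on these phantoms shows: the pipeline's contracts,
formulas, leakage protections, calibration under the null (cross-validated
AUC near 0.5 when no signal exists) and its ability to recover strong
synthetic signal. What they cannot show: performance on real T2-weighted
MRI — the phantoms have no bias fields, coil profiles, partial-volume
mixtures, anatomy, or inter-observer contour variability, so the published
patient-cohort AUC values are out of reach by design and are not asserted
anywhere.

## Numerical choices and degenerate inputs

* Gray-level matrices are built by vectorised array shifts; the test suite
  proves them equal to brute-force pair/run/zone/dependence enumeration
  oracles at 1e-10 relative tolerance on random small ROIs.
* Run/zone/dependence matrices on a single-voxel or constant ROI collapse
  gracefully (one run, one zone, dependence 1); a ROI with no valid
  co-occurrence pair in any direction falls back to the certain one-level
  matrix.
* `NaN`/`Inf` in an assembled domain vector (possible only through
  pathological input) is replaced by 0 with a warning, so downstream
  matrices stay finite.
* All randomness (weights, splits, generators) derives from integer seeds
  through one multiplicative-congruential child-seed scheme; outputs are
  byte-identical across runs with the same base seed.
* Empty ROIs, grid misalignments, non-positive spacings, unknown clinical
  categories, single-class training data and wrong feature widths all
  raise classed conditions (`hybridpcr_*_error`) rather than partial
  results.

## Known limitations

* The catalogue is the 107-entry standard set; the published 109-entry
  appendix cannot be reconstructed from the available text, so published
  per-feature values cannot be compared one-to-one.
* The backbone is shipped with seeded random weights; with them the
  abstract features are structurally valid but not semantically
  "ImageNet-like". Supplying real pretrained weights is supported but not
  required by any test.
* Fine-tuning updates only a classification head, not the convolutional
  body.
* Phantom realism is deliberately minimal (see above).
* Mesh-based shape features inherit a small inward bias from occupancy
  smoothing for ROIs only a few voxels across.
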