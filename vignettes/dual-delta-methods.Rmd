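---
title: "Dual-delta modelling of longitudinal CT nodules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-delta modelling of longitudinal CT nodules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
model, its assumptions, the tunable parameters, the numerical conventions,
and the places where the design was genuinely open and a choice had to be
made. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The model

A subject contributes a baseline and a follow-up CT scan of the same lung
nodule, an intratumoral mask, and a binary histopathological label (we use
STAS — spread through air spaces — as the motivating phenotype). The working
hypothesis is that the *dynamics* of the nodule between the two scans —
anisotropy of growth and change of internal heterogeneity — carry label
information that no single timepoint carries. The package therefore builds
four feature blocks per subject:

* **classic intratumoral / peritumoral** — the 851-feature radiomics
  inventory of the *follow-up* scan (the last scan before surgery) for the
  tumour mask and for the 3 mm peritumoral ring;
* **delta intratumoral / peritumoral** — the per-feature time slope
  `(I_f − I_b) / (t_f − t_b)` in units of feature-per-day.

Time is measured in days everywhere; mixed week/month/year eligibility
windows are converted when manifests are read. The concatenated "dual table"
has 4 × 851 = 3404 columns; the delta-DL channel appends 30 deep features.

### Radiomics inventory

The inventory mirrors the standard IBSI-style profile: 14 shape, 18
first-order, 24 GLCM, 14 GLDM, 16 GLRLM, 16 GLSZM, 5 NGTDM features on the
original image, and the 93 non-shape features recomputed on the 8 sub-bands
of a one-level 3-D stationary wavelet decomposition (851 per region and
timepoint). The texture-matrix builders are compiled code; the feature
formulas are R. Conventions that the numbers depend on:

* **Discretisation** — fixed bin width, default 25 HU, a common chest-CT
  setting (`radiomics_config(bin_width = )`). If a filtered image's range
  would exceed `max_gray_levels` (256) bins, the width is widened to span it.
* **Aggregation** — the co-occurrence matrix is summed over all 26 angles
  before features are computed (rather than averaging per-angle features);
  run-length matrices sum over the 13 unique directions; zones and
  dependences use 26-connectivity; the GLDM similarity tolerance defaults
  to 0.
* **Shape** — voxel-based approximations: volume by voxel counting, surface
  area by exposed-face counting, axis lengths from PCA eigenvalues
  (4·√λ), maximum diameters from boundary-voxel pairs. No surface mesh is
  built, so values differ slightly from mesh-based engines; all shape
  features are intensity-invariant by construction.
* **Wavelet family** — Haar filters, undecimated, reflective boundaries, with
  the sub-band letter order `x, y, z`. The sub-band labels (LLL…HHH) are
  fixed; the family is a documented default, chosen for its exact
  integer-friendly filters.
* **Resampling** — `radiomics_config(resample_mm = )` resamples to isotropic
  spacing before extraction (trilinear for images, nearest for masks). The
  default is native spacing because the phantom substrate is already
  isotropic; set 1 mm for clinical data with anisotropic slices.

Min–max normalisation is always fitted on the training rows only and the
fitted ranges applied to held-out rows (which may leave [0, 1]). The paper
trail for why this matters is the leakage-canary test: a feature equal to
the label on one fifth of the rows must not raise cross-validated AUC.

### Reproducibility gate

Repeated delineations (within-rater repeats, between-rater delineations) are
summarised per feature by ICC(2,1): two-way random effects, absolute
agreement, single measurement, from the ANOVA mean squares. Raters are
modelled as random because they are interchangeable observers; the
absolute-agreement form penalises systematic rater offsets, which is what
reproducibility of a feature value requires. A feature enters selection only
when both intra- and inter-rater ICC exceed the threshold (default 0.75,
strict inequality). A zero-variance table is defined as ICC = 1 with a
warning (agreement is perfect). Whether delta features are gated on their
own repeated-delineation ICCs or inherit their parent feature's gate is
configurable; the pipeline computes the gate on whichever table enters
selection, and `icc_filter()` accepts any report covering the columns.

### Views, registration, delta-images

For each body axis the slice maximising in-plane mask area is chosen (ties
to the lowest index, documented), and the smallest bounding square plus a
margin (default 4 px) is cropped. For a *pair* of scans the two crops share
one window (the union box); without that, cropping would silently remove the
very motion registration is supposed to estimate. Three registration method
classes are provided: Harris-corner keypoint matching with a deterministic
two-point consensus vote and closed-form similarity fit; monomodal intensity
(mean squares); and multimodal (mutual information, 32-bin joint histogram).
Intensity methods are initialised by FFT cross-correlation and refined by
Nelder-Mead over translation/rotation/log-scale; plain cross-correlation is
used rather than whitened phase correlation because the latter is unstable
on smooth band-limited images. The default transform family is rigid +
isotropic scale; rigid and translation-only are flags.

Safeguards: registration that would *lower* SSIM against the unregistered
pair by more than 0.02 returns the identity instead, and on a static
noiseless pair the entire view pipeline produces exactly-zero delta images.
When the direct SSIM falls below the fallback threshold (default 0.5), or
keypoint matching finds fewer than three consistent pairs, the transform is
re-estimated on spine crops from the same slices (rigid only — vertebrae do
not grow) and applied to the nodule view. Rotation is applied about the view
centre, so the fallback is exact for translation-dominant motion — the case
it exists for.

Delta-images are follow-up minus warped baseline, clipped at ±200 HU,
mapped to [0, 1] (zero difference → 0.5) and resized to the network input
(default 64 × 64; 227 × 227 mirrors the classic AlexNet profile).

### The delta-DL network

A reduced AlexNet-style CNN: three 3 × 3 conv blocks (8/16/32 channels, each
ReLU + 2 × 2 max-pool), a fully-connected **feature layer of 10 neurons per
view**, and a 2-way softmax head — ~26k parameters at the 64 × 64 default,
kept deliberately desk-scale. One network is shared across the three views
with a constant view-tag channel (x = 0, y = 0.5, z = 1); per-view networks
are possible by training three instances. Training is mini-batch SGD with
momentum (defaults 20 epochs, lr 0.01, momentum 0.9, batch 32,
inverse-frequency class weights) — declared configuration, not a claim about
any reference implementation. Forward/backward passes are hand-written on
BLAS matrix operations (im2col); gradients are verified against central
finite differences in the test suite, and runs are bit-deterministic for a
fixed seed. Grad-CAM weights the final conv activations by the spatial mean
of the class-score gradient, ReLUs the sum, upsamples, and min–max
normalises; an all-constant map normalises to zeros by convention.

In the pipeline the CNN is trained on a stratified half of the cohort and
features are extracted for everyone; the downstream cross-validation of the
feature table therefore sees deep features whose extractor was fitted partly
on its test subjects' *images* but never on their labels held out within a
fold. For strict end-to-end claims, train on a fully disjoint split.

### Selection, classifiers, evaluation

`default_selector_registry()` (45 entries) and
`default_classifier_registry()` (32 entries) are built from ~12 selector
families (variance, t, Wilcoxon, Kruskal, univariate AUC, Pearson/Spearman,
mutual information, Fisher score, ReliefF, random-forest importance,
redundancy-aware correlation filtering, FDR t-tests, LASSO/elastic-net) and
~10 classifier families (logistic and penalised variants, LDA/QDA, four SVM
kernels, kNN, naive Bayes, CART, random forests, shallow neural networks,
gradient boosting), with hyperparameter variants counted as distinct
entries. The registry *cardinalities* (45 × 32 = 1,440) are the contract;
the exact identities are configurable because no canonical list exists to
mirror. Every entry is functional and crash-isolated inside `run_grid()`
(a failing cell is a missing cell, not a failed grid).

`crossval_auc()` draws fresh stratified folds per replication; inside every
training fold the normalisation, the selector and the classifier are fitted
in that order, and the held-out fold only passes through fitted transforms.
AUC is computed with a fixed score orientation (higher = positive) so
chance-level models are not optimistically flipped — the null-label test
would catch that. Confidence intervals are percentile intervals over
replications (default 40; smaller in tests for runtime). "LASSO (alpha =
0.5)" is implemented as elastic-net mixing 0.5 with the penalty chosen at
the minimum cross-validated error ("MSE_min"; a 1-SE rule is a flag).
Propensity-score matching (logistic propensity on six shape/first-order
covariates — volume, surface area, sphericity, maximum 3-D diameter, mean,
entropy, a documented stand-in choice — greedy 1:1 nearest-neighbour on the
logit, caliper 0.2 SD) yields the balanced-cohort alternative. Follow-up
interval subgroups use `[21, 91)`, `[91, 365)`, `[365, 730)` days (A/B/C),
half-open by convention.

## The phantom: what it emulates, what it does not

`phantom_spec()` renders an ellipsoidal nodule (≈ −50 HU) carrying a smooth
per-subject random texture field, in lung parenchyma (−800 HU) with a rigid
spine block (+300 HU), under additive Gaussian noise. Growth is exponential
per axis (`r_i(t) = r_i0 exp(g_i t)`; linear behind a flag) — a stand-in
model chosen for scale-free per-day rates, since the measured quantity is
growth's *imprint* on features, not the growth law itself. The texture field
is fixed in material coordinates, so the same anatomy is seen at both
timepoints up to growth, motion, amplitude drift and fresh noise. Masks are
the analytic ellipsoid — truth never passes through segmentation.

The default class recipes draw the *follow-up* state — radii U(4.5, 7.5) mm
per axis, texture amplitude U(20, 40) HU, interval U(30, 180) days, volume
growth rate U(0.0015, 0.009)/day, translation U(−3, 3) mm per axis — from
identical distributions for both classes, and derive the baseline by inverse
growth. Negatives split the volume growth isotropically with constant
heterogeneity; positives split it anisotropically (uniform random axis
weights) and drift their heterogeneity upward by 0.05–0.15 HU/day toward
the class-matched follow-up amplitude. Single-timepoint marginals are
therefore identical across classes by construction, and the acceptance
experiment measures exactly the intended contrast: classic-only models at
chance, delta-informed models far above it. Growth magnitudes sit in the
range of slow-growing early lung tumours (volume doubling times of roughly
100–500 days); noise (5 HU) and motion (±3 mm) are modest but nonzero so
registration and texture features are genuinely stressed.

What the phantom does **not** emulate: respiratory motion and its artifacts,
scanner reconstruction kernels, ground-glass/solid composition, vessels and
bronchi crossing the mask, rater anatomy-driven (rather than morphological)
segmentation error. Passing tests therefore demonstrate correctness of the
machinery and the *direction* of the dual-delta effect under controlled
dynamics — not clinical performance. Real-cohort AUCs are out of reach
without patient data and are not claimed.

## Problem sizes and numerical choices

The test suite and acceptance script use deliberately desk-scale problems
chosen as representative rather than exhaustive: 64³ voxel phantoms,
cohorts of 4–200 subjects (200 for the separation experiment, 120 in the
acceptance script), 3–10 cross-validation replications where the full
pipeline defaults to 40, and 10–15 CNN epochs. Tolerances: exact oracles at
10⁻¹⁰–10⁻¹² (slope algebra, ICC mean squares, pair-counting AUC), 10⁻⁸ for
SSIM vs the windowed formula, 10⁻⁴ relative for finite-difference gradients,
0.5 px / 1° for rigid-transform recovery. Ties: maximal-area view slices and
max-pool gradients both break toward the first (lowest) index. Degenerate
inputs error early and loudly: empty masks, single-voxel regions, unknown
morphological operators, non-increasing timepoints, single-class training
labels, empty ICC survivor sets.

## Known limitations

* 2-D view-level registration (three orthogonal planes), not 3-D volumetric
  or deformable registration; out-of-plane rotation is only approximated.
* The spine fallback assumes the landmark and nodule share one rigid motion
  and is exact only for translation-dominant cases.
* Vessel/bronchus exclusion is approximated by morphological opening.
* Mesh-free shape features deviate slightly from mesh-based engines.
* NIfTI is the supported volume format (masks: NIfTI; DICOM series must be
  converted upstream, with acquisition dates supplied via the manifest).
* The registry entries are representative families, not a canonical list;
  cardinality and mechanics, not identities, are the contract.
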