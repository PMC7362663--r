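---
title: "Methods: mismatch labeling and two-level tissue classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mismatch labeling and two-level tissue classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific model behind `penumbra`, the
parameter defaults and why they were chosen, what the synthetic phantom
does and does not emulate, and the numerical conventions a maintainer
needs to know.

## The problem

In acute ischemic stroke, the infarct core (IC) is irreversibly damaged
while the surrounding hypoperfused penumbra (IP) is still salvageable.
The conventional delineation needs two acquisitions: a diffusion scan for
the core and a contrast-bolus perfusion scan for the hypoperfused region,
whose spatial difference — the perfusion–diffusion mismatch (PDM) — is the
penumbra. The pipeline implemented here (i) reconstructs that conventional
PDM labeling in a rodent permanent-occlusion setting, and (ii) trains a
voxel-wise classifier that predicts all three tissue classes from the
diffusion tensor data alone, using the PDM labels as supervision. If that
works, a single DTI acquisition can stand in for the two-modality
protocol.

## Pipeline model, stage by stage

**DTI metrics** (`compute_dti_metrics`). Inputs are the sorted tensor
eigenvalues per voxel (mm²/s). Besides MD, AD, RD and FA we compute the
isotropic/deviatoric decomposition magnitudes: pure anisotropy
q = √Σ(λᵢ−MD)² and total magnitude L = √Σλᵢ², linked by
FA = √(3/2)·q/L — an identity the test suite checks to 1e−12 on random
tensors, which guards both formulas at once. All-zero tensors get FA = 0
and a QC count rather than NaN.

**Smoothing and normalization** (`gaussian_smooth`, `normalize01`). Maps
are smoothed within-slice by a normalized Gaussian kernel whose weights
are renormalized over in-mask voxels, so out-of-brain neighbours never
leak in. Note that this renormalization conserves the global sum only
away from mask boundaries; the suite asserts conservation for
interior-supported maps, which is the exact statement. Defaults σ = 1
voxel, truncation 2σ; the kernel size is a free choice since only
"Gaussian weighted mean" smoothing is specified upstream. Whether to
smooth before or after metric derivation is ambiguous in the source
protocol; we smooth the derived maps. The [0,1] rescaling is per-rat,
per-map over the whole brain mask; it exists for inter-animal display
comparability and is *not* used for thresholding or features, which are
ratio-based and would be distorted by it.

**Perfusion** (`signal_to_concentration`, `fit_gamma_variate`,
`compute_cbf`). Concentration C(t) = −ln(S/S₀)/TE with S₀ the
baseline-window mean; the gamma-variate bolus model is fitted by
Levenberg–Marquardt least squares from the sample just before detected
bolus arrival (first point above baseline mean + 3 SD) to the first
post-peak sample below 10% of peak, which excludes recirculation. Starting
values are moment-matched: α = 3, β = (time-to-peak − t₀)/α, K from peak
height. rMTT = β(α+1) is measured from bolus arrival, not from acquisition
start — including t₀ would make rCBF depend on injection timing. No
arterial input function deconvolution is attempted: only *relative* CBF is
needed, and the 46% threshold and all features are ratios against the
contralateral hemisphere, so the unknown proportionality constant cancels.
Identical curves are fitted once and reused (a pure cache, exact on
noiseless phantoms). Failed fits are flagged and excluded with a QC count.

**PDM labeling** (`threshold_ic`, `threshold_perfusion`,
`derive_pdm_labels`, `contiguity_correction`). IC: MD strictly below
(1 − 0.30) × contralateral-hemisphere mean, ventricles excluded. Deficit:
rCBF strictly below (1 − 0.46) × contralateral mean. IP = deficit ∧ ¬IC;
NT = remaining ipsilateral tissue. Two distinct contralateral references
are deliberate: reduction thresholds use the *hemisphere mean* (the rules
are phrased against the hemisphere), whereas relative features use the
*voxel mirror* (phrased against homologous tissue). Strict `<` everywhere:
a voxel exactly at threshold is not lesion. Core voxels outside the
perfusion deficit keep the IC label (diffusion lesion takes precedence)
with a QC count. The contiguity rule — reassign a voxel when ≥ 6 of its 8
in-slice neighbours share one different class, one simultaneous pass — is
our minimal deterministic reading of "contiguity correction"; the
underlying references do not specify the algorithm, so the rule is
config-exposed. Coregistration between the rCBF and MD grids is the
identity here (phantom grids are aligned by construction); true
registration is out of scope.

**Features** (`rat_feature_matrix` and friends). 110 = 18 + 90 + 2:

* 18 relative-DTI: six metrics at the voxel, the slice below and the slice
  above (nearest-slice replication at stack edges).
* 90 histogram: per metric, an 11-bin normalized histogram of relative
  values in a 7×7 coronal window (bins equal-width on [−1, 1], outliers
  clipped into end bins — relative reductions are bounded below by −1)
  plus its skewness and kurtosis, and skewness/kurtosis of a 3×3 window in
  the axial projection reconstructed from the coronal stack. Bin counts
  come from the coronal window only: 49 samples support 11 bins, the
  axial window's 9 do not, so it contributes moments only. Moments are
  population moments (no bias correction), kurtosis is Pearson m₄/m₂²,
  and constant windows get skew = kurt = 0 by convention.
* 2 Mahalanobis distances of the voxel's relative-DTI vector to the
  training core distribution, in the 6-dim same-slice and 18-dim spaces.
  The total of 110 is stated upstream but its composition is not; this
  split is our declared reconstruction, visible in `feature_columns()`.

The core covariance gets a ridge of 1e−6 × mean diagonal so degenerate
clouds stay positive-definite. Histogram features are computed on the raw
relative metrics (not renormalized maps). Relative metrics are defined as
0 where the mirror value is non-positive, with a QC count, so matrices
contain no NaN/Inf by construction (asserted at build time).

**Classification** (`train_two_level`, `train_single_level`). Level 1:
IC vs non-IC on the 18 DTI features (the Mahalanobis block is excluded
entirely at this level). The core distribution is then fitted on training
IC voxels only, Mahalanobis features are computed for the non-IC training
rows, and level 2 separates IP vs NT on all 110. Backends: SVM (radial
kernel, C = 1, kernel scale by the median pairwise-distance heuristic),
KNN (k = 5), decision tree (rpart defaults); hyperparameters are declared
choices, not tuned, since none are reported upstream. Features are
standardized with training-set mean/SD before SVM/KNN — map-level [0,1]
normalization does not standardize engineered features. No class
reweighting by default. Training rows per level are capped at 4000 by a
stratified seeded subsample to keep kernel fits tractable; the cap is a
config argument. Everything is deterministic given the seed.

**Validation** (`evaluate_loocv`, `kfold_split`, volume functions). One
LOOCV fold per animal; the held-out rat's voxels touch neither classifier
fit nor the core-distribution fit, which the report's fold metadata makes
assertable. A stratified seeded `kfold_split` (k = 5) is provided for
training-pool cross-validation. AUC uses the rank statistic with ties at
½; volume equivalence uses two-sided Mann–Whitney tests on per-rat
volumes; slice-to-slice correspondence uses Pearson correlation (the
estimator is unnamed upstream; Pearson is the conventional choice for
volume scatter). Accuracy conventions: IC-vs-nonIC over all voxels,
IP-vs-NT over voxels non-IC under both labelings, 3-class over all
voxels.

## The phantom: what it emulates and what it does not

`phantom_spec()` defaults encode the emulated study conditions: 14 rats,
5 coronal slices, 128×128 grid at 0.16 mm (the zero-filled acquisition
matrix), DSC with TR 1 s, TE 20 ms, 300 repetitions, bolus arrival ~30 s
after acquisition start. Tissue effect sizes follow the reported
hyperacute biology: 40% eigenvalue reduction in the core, 10% in the rim,
uniform across eigenvalues (which preserves the near-symmetric FA seen at
0.5 h). Per-tissue CBF drops are *not* reported upstream (only the 46%
viability threshold), so the defaults — 80% core, 60% rim, 10%
ipsilateral NT — are threshold-consistent choices: the rim must fall
below and normal tissue above the 46% cut for the ground truth to be
realizable at all, and `phantom_spec()` rejects configurations violating
that.

Geometry: a midline-symmetric elliptical brain with two fixed
periventricular high-MD (2.5× NT) regions; per rat, a random ellipsoidal
core spanning contiguous slices with a thin in-plane penumbral rim (1–3
voxels, matching the "small, even sparse rim at the margin of a large
core" morphology of suture occlusion), placed in a random hemisphere. The
normal-tissue eigenvalue field (1.2, 0.9, 0.6)×10⁻³ mm²/s carries a
smooth, midline-symmetric anisotropy modulation with constant MD, standing
in for white-matter variation. Ground-truth labels are iterated to a fixed
point of the contiguity rule, which makes the labeling stage's single
cleanup pass a no-op on noiseless data — that is what makes the
"noiseless round-trip is voxel-exact" property well-posed.

Noise is additive Gaussian on eigenvalues (clipped at 0, re-sorted) and on
signal; defaults 1% of NT mean diffusivity and 1% of the baseline signal.
Optionally (`kspace_zerofill = TRUE`) maps are generated at half
resolution and zero-filled in the spatial-frequency domain, emulating the
acquisition's interpolation smoothness; default off since it only blurs.

Not emulated: anatomical rat anatomy, Rician noise, motion, partial
volume, heterogeneous CBF within tissue classes, arterial input
variability, misregistration between DTI and DSC grids. Consequently,
passing tests demonstrate *internal correctness and recoverability under
the stated generative model*, not real-data performance; the upstream
study's printed accuracies were measured on scanner data that is not
available, and nothing here claims to reproduce them numerically.

## Study conditions used by the shipped experiments

The test suite and `scripts/acceptance.R` run three desk-scale cohorts,
all 48×48 × 3 slices so the full pipeline (including ~4,000 gamma-variate
fits per rat) completes in minutes on one CPU:

* a noiseless 4-rat cohort for the exact labeling round-trip;
* a low-noise 8-rat cohort (1% eigenvalue noise) for classifier recovery,
  volume correlation and Mann–Whitney equivalence — the well-separated
  condition under which the cascade should be near-perfect;
* a realistic-noise 8-rat cohort (5% eigenvalue noise, 1-voxel rim) on
  which the two-level cascade is contrasted with the single-level
  baseline. The thin rim and ~5% class share make IP the hard minority
  class; this is where the hierarchical design's advantage (level 2
  trains only on non-IC voxels, with Mahalanobis and texture context)
  shows, mirroring qualitatively the upstream contrast between the
  cascade's and the flat baseline's IP sensitivity.

These sizes, noise levels and seeds were fixed when the experiments were
designed; `analysis/01–06` run the same conditions as a narrative
workflow and write their tables under `results/`.

## Numerical conventions and degenerate inputs

* Thresholds strict (`<`); ties are non-lesion.
* Histogram bin edges half-open, last bin closed; values clipped into end
  bins.
* Zero-variance windows: skew = kurt = 0; constant maps refuse [0,1]
  normalization with an informative error.
* Gamma fits: flat or peakless curves return `converged = FALSE` and the
  voxel is excluded downstream with a QC count; `rmtt > 0` is guaranteed
  for converged fits (α, β > 0 bounds).
* Eigenvalues are re-sorted on ingest; negative values inside the mask are
  an error, negative noise excursions in the generator are clipped first.
* Seeds: the cohort is a pure function of `phantom_spec` (including its
  `seed`); classifier training takes its own seed; LOOCV fold f uses
  `seed + f`.

## Known limitations

* The 110-feature composition and the Mahalanobis feature spaces are
  reconstructions; if the original split differed, absolute feature
  indices (not the methodology) would change.
* The contiguity rule is a declared stand-in for an unspecified published
  procedure.
* Single-slice 2-D smoothing and in-plane-only rims mean through-plane
  structure is weaker than in real volumes.
* SVM hyperparameters are sensible defaults, not tuned; on real data one
  would cross-validate them inside the training pool (the 5-fold splitter
  is provided for exactly that).
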