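# penumbra

Voxel-wise segmentation of the acute stroke hemisphere into **infarct core
(IC)**, **ischemic penumbra (IP)** and **normal tissue (NT)** from diffusion
tensor imaging (DTI) and dynamic susceptibility contrast (DSC) perfusion
MRI, in a rodent permanent-MCAO setting. The package implements the full
analysis as tested, reusable R functions, together with a seeded synthetic
rat-brain phantom generator so every stage — and the pipeline end to end —
can be exercised and validated without scanner data.

Intended users: imaging methodologists and preclinical stroke researchers
who want a reproducible reference implementation of mismatch-based tissue
labeling and hierarchical voxel classification.

## What it computes

**DTI metrics.** From sorted eigenvalues λ₁ ≥ λ₂ ≥ λ₃ of the diffusion
tensor: MD = (λ₁+λ₂+λ₃)/3, AD = λ₁, RD = (λ₂+λ₃)/2, the pure anisotropy
q = √Σ(λᵢ−MD)², the tensor magnitude L = √Σλᵢ², and FA = √(3/2)·q/L.
Maps can be smoothed with a mask-renormalized Gaussian kernel and linearly
rescaled to [0, 1].

**Perfusion.** DSC signal is converted to concentration, C(t) =
−ln(S(t)/S₀)/TE, and fitted per voxel with a gamma-variate bolus model
K(t−t₀)^α e^{−(t−t₀)/β}. Closed forms give rCBV = Kβ^{α+1}Γ(α+1), rMTT =
β(α+1) (first moment from bolus arrival), and rCBF = rCBV/rMTT by the
central volume principle.

**PDM labeling.** IC = ipsilateral voxels with MD below 70% of the
contralateral-hemisphere mean (ventricles excluded); perfusion deficit =
rCBF below 54% of the contralateral mean; IP = deficit minus IC; NT = the
rest of the ipsilateral hemisphere; followed by an 8-neighbour contiguity
correction that removes isolated mislabeled voxels.

**Features.** Each voxel gets 110 features: 18 relative DTI metrics
(rX = (X − X_mirror)/X_mirror for six metrics at the voxel's slice and the
two adjacent slices), 90 windowed histogram features (per metric: 11
normalized bin counts plus skewness/kurtosis in a 7×7 coronal window, and
skewness/kurtosis in a 3×3 window of the reconstructed axial projection),
and 2 Mahalanobis distances from the voxel's relative-DTI vector to the
training distribution of core voxels (6-dim and 18-dim variants).

**Classification and validation.** A two-level cascade — level 1 separates
IC from non-IC on the 18 DTI features; level 2 separates IP from NT on all
110 — with SVM, KNN or decision-tree backends, against a single-level
three-class baseline. Validation is leave-one-out cross-validation over
animals (no voxel of the held-out rat touches either classifier fit or the
core distribution), with accuracy / sensitivity / specificity / AUC,
slice-to-slice volume correlation, and Mann–Whitney volume equivalence
tests.

## Worked example

```r
library(penumbra)
spec <- phantom_spec(n_rats = 4L, n_slices = 3L, grid = c(48L, 48L), seed = 7L)
res <- run_pipeline(spec, backend = "svm", seed = 1L, smooth_sigma = 0,
                    max_train_voxels = 3000L)
print(res)
```

```
Two-level svm LOOCV over 4 rats, 7152 voxels
  IC vs non-IC accuracy: 100.0%  (AUC 1.000)
  IP vs NT accuracy:     98.9%  (AUC 1.000)
  3-class hemisphere accuracy: 99.0%
  Volume Mann-Whitney p (IC/IP/NT): 1 / 1 / 0.769
```

Reading: on a 4-rat synthetic cohort with 1% eigenvalue noise, the cascade
recovers the core perfectly on held-out animals, classifies IP vs NT at
98.9% among non-core voxels, and the per-rat volumes it estimates are
statistically indistinguishable from the ground truth (all Mann–Whitney
p ≫ 0.05). Under harder, realistic noise the separation degrades —
`analysis/05_single_level_contrast.R` shows the single-level baseline's IP
sensitivity collapsing (≈42%) while the cascade stays high (≈93%).

## Analysis workflow

The study itself is organized as numbered drivers over the package:

```
analysis/01_simulate.R              # seeded cohorts + NIfTI export
analysis/02_maps_and_labels.R       # DTI metrics, perfusion fits, PDM labels
analysis/03_features.R              # 110-feature voxel matrices (CSV)
analysis/04_loocv_two_level.R       # two-level SVM LOOCV
analysis/05_single_level_contrast.R # cascade vs flat baseline
analysis/06_volumes.R               # volume correlation + equivalence tests
```

Each writes its tables under `results/`. Run them in order with `Rscript`.

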