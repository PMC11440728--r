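---
title: "Methods: radiomics and neural Cox survival modeling in periSurv"
author: "periSurv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomics and neural Cox survival modeling in periSurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`periSurv` predicts progression-free survival (PFS) after immunotherapy
in lung cancer from three feature families — clinical covariates,
intratumoral CT radiomics, and peritumoral-vasculature radiomics — via
a neural Cox proportional-hazards model. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic phantom cohort does and does not establish.

## 1. Image preprocessing

CT volumes are resampled to 1 mm isotropic voxels (`resampleIsotropic`,
trilinear interpolation for intensities, nearest-neighbor for masks so
binary topology survives) and intensity-standardized to zero mean and
unit SD over the whole volume (`zscoreStandardize`). Clinical CT comes
with slice thicknesses up to 5 mm and sub-millimetre in-plane pixels;
isotropic resampling makes 3D texture offsets and Hessian scales
geometrically meaningful. The resample-then-standardize order is a
choice (the reverse is nearly equivalent because Z-scoring is affine);
we standardize last so interpolation happens on the native values.

## 2. Wavelet subbands

`waveletDecompose` applies a single-level **stationary (undecimated)
separable Haar transform**: a low-pass (averaging) or high-pass
(differencing) filter along each axis, giving the canonical eight
subbands LLL ... HHH. Three choices deserve comment:

* *Haar*: orthogonal, two taps, unambiguous boundary behavior; the
  family is fixed here rather than configurable because every oracle
  (energy, reconstruction) is exact for it.
* *Undecimated*: subbands keep the shape and spacing of the input, so
  the same tumor mask indexes every image set. This matches common
  radiomics practice, where wavelet "filtered images" are same-size
  volumes.
* *Periodic boundary with filter taps (1/2, ±1/2)*: with this
  normalization the summed squared coefficients over the eight subbands
  equal the squared input exactly, and the inverse transform is exact —
  both are tested to machine precision rather than to a tolerance.

## 3. Intratumoral features (593)

The feature list is fixed by `intratumoralManifest()` (also shipped as
`inst/extdata/manifest_intratumoral.json`): per image set (original + 8
subbands) 14 histogram, 22 GLCM, 11 GLRLM and 17 LBP features, plus 17
mask-only geometry features — 9 × 64 + 17 = 593.

* **Quantization**: fixed bin *count* (64) over the ROI min–max range.
  After Z-scoring, absolute intensity units are gone, so a fixed bin
  *width* would be ill-defined.
* **GLCM**: distance-1 co-occurrences accumulated over the 13 unique 3D
  directions, symmetrized and merged before normalization (the
  aggregation with the fewest free choices). Degenerate conventions:
  the correlation of a single-cell matrix is 1; logs are base 2.
* **GLRLM**: run-length matrices per direction, features averaged over
  the 13 directions. Runs are maximal same-level segments of in-mask
  voxels along lattice lines; a mask gap breaks a run. Both GLCM and
  GLRLM are tested against exhaustive enumeration oracles on small
  grids.
* **LBP**: no canonical 3D LBP exists, so the package uses the count of
  strictly-greater neighbors among the 26-neighborhood — a rotation
  invariant — pooled from 27 possible counts into 16 bins, plus the
  histogram entropy. Every code is checkable by per-voxel enumeration.
* **Geometry**: volume, marching-tetrahedra surface area (the binary
  mask is smoothed with a one-voxel Gaussian and the 0.5 iso-surface
  triangulated with interpolated vertices — a plain voxel-face or
  midpoint mesh overestimates a sphere's area by ~30%, while this mesh
  is within ~2%), surface/volume, maximum 3D diameter (largest pairwise
  surface-voxel distance plus one voxel diagonal, so a single voxel
  yields its diagonal), axis extents, PCA axis lengths, sphericity and
  friends. Skewness and kurtosis of constant regions are defined as 0
  to keep degenerate ROIs finite.

## 4. Peritumoral-vasculature features (91)

The segmentation chain (`segmentVessels`) follows the classic recipe:

1. **Vesselness** (`vesselness`): Frangi-type response from the
   scale-normalized Hessian (second central differences of the
   Gaussian-smoothed volume, multiplied by σ²) with α = β = 0.5,
   γ = half the maximum Hessian norm per scale, bright-tube sign
   convention, maximum over scales. Default scales 1–4 mm span the
   calibre of peritumoral vessels at 1 mm resolution; scales below the
   voxel size are clamped with a warning. Eigenvalues come from the
   closed-form trigonometric solution for symmetric 3×3 matrices,
   vectorized over the volume.
2. **Otsu threshold** on the in-lung response (256-bin exhaustive
   between-class-variance maximization).
3. **Morphological cleanup**: binary opening with a 1 mm ball (both
   erosion and dilation run on the exact Euclidean distance transform)
   and removal of 26-components below 27 voxels.
4. **Peritumoral cube**: the tumor bounding box extended 25 mm per side
   per axis, clipped to the grid; vessel voxels are restricted to
   (lung ∩ cube) \ tumor — the vasculature *around*, not inside, the
   tumor. Vesselness is computed on the whole lung and cropped
   afterwards.
5. **Lung mask**: an externally supplied mask is used verbatim;
   otherwise `lungMaskFallback` labels low-intensity components, fills
   internal holes (vessels, nodules) and re-includes the tumor.

**Centerlines** (`extractCenterlines`): distance-ordered homotopic
thinning in compiled code — voxels are visited in increasing
distance-to-surface order and removed only when they are simple points
(Bertrand's 26/6 topological numbers) and not curve endpoints, with six
directional sub-iterations per distance level so opposite faces erode
symmetrically (one-sided erosion otherwise leaves off-axis medial
sheets). Residual spurs shorter than max(2 mm, 1.5 × local radius) are
pruned iteratively with re-partitioning. Branches split at junction
voxels (≥ 3 skeleton neighbors); adjacent junction voxels merge into
one junction. Each centerline point is finally refined to the centroid
of its local vessel cross-section (a slab perpendicular to the local
tangent), which removes most sub-voxel staircase jitter — without this
step, third-derivative quantities are unusable.

**Branch geometry** (`branchGeometry`): arc-length resampling at
0.5 mm, Gaussian smoothing along the curve, central differences, and
the Frenet formulas κ = |r′×r″|/|r′|³, τ = (r′×r″)·r‴/|r′×r″|².
Numerical safeguards:

* The pointwise τ is ill-conditioned wherever κ ≈ 0 (the denominator
  |r′×r″|² vanishes). The per-branch `mean_torsion` therefore uses the
  curvature-weighted signed estimator |Σ(r′×r″)·r‴| / (Σ|r′×r″|² + ε),
  with ε corresponding to a curvature floor of 0.02 mm⁻¹ (curves
  flatter than a 50 mm radius carry no usable torsion signal). The
  estimator is exact for a helix, where τ is constant, and shrinks to 0
  on straight branches instead of rectifying noise.
* Smoothing defaults: 1 mm for analytic curves (the helix oracle is
  recovered within ~1%), 1.5 mm inside `extractVesselFeatures` where
  the input is a raster-derived centerline.
* The first/last three samples are excluded from all summaries
  (boundary differences), and torsion needs ≥ 5 points.

`extractVesselFeatures` assembles the fixed 91-feature vector
(`vesselManifest()`): {mean, SD, skewness, kurtosis, median} over
branches of 12 geometric quantities plus total vessel volume (61), and
counts/densities plus the same five statistics over five arrangement
quantities (30). An empty tree returns all zeros with an `empty` flag
rather than NAs, so downstream matrices stay numeric.

**Outlier filter** (`outlierFilter`): per feature, mean and SD are
estimated on the *training split only* and the fraction of all subjects
beyond 3 SDs is counted; features with a fraction strictly above 20%
are dropped. The reference statistics must come from a subset: by
Chebyshev's inequality at most ~11% of any sample lies beyond 3 SDs of
its own moments, so a within-sample 20% rule could never fire.

## 5. Feature selection

`splitCohort` partitions subjects 55/15/30 (train/validation/test) by
simple random sampling with largest-remainder rounding (206 → 113/31/62).
Screening (`screenFeatures`) applies univariate Cox regression
(Breslow ties) to continuous features and Pearson chi-squared (no
continuity correction) against the progression indicator to categorical
ones, keeping p < 0.05 with no multiplicity adjustment — the gate is
deliberately liberal because the second step prunes interactions.
`sequentialForwardSelection` then greedily adds the candidate that
maximizes the validation C-index of a linear Cox model fitted on the
training split, breaking exact ties by the smaller screening p-value,
and stops at the first non-improving step (patience 1) or 15 features.
A linear Cox inner model keeps the greedy loop tractable; the neural
model is trained once, afterwards, on the selected set. If screening
passes nothing, the pipeline falls back to the three smallest p-values
with a warning rather than failing.

## 6. The neural Cox model

`trainSurvivalNetwork` fits a multilayer perceptron risk score under
the event-averaged negative Breslow partial log-likelihood, which keeps
the proportional-hazards structure while letting the log-hazard be
nonlinear in the inputs. Defaults (all exposed in `networkSpec` and
grid-searchable with `gridSearch`, which breaks exact validation
C-index ties by shorter recorded training time):

| parameter | default | note |
|---|---|---|
| hidden layers | 32, 32 | SELU activation |
| dropout | 0.2 | inverted, deterministic given seed |
| weight penalty | 1e-4 | L2 on weights, not biases |
| optimizer | full-batch Adam, lr 0.01 | cohort sizes here are hundreds |
| early stopping | patience 20 on validation C-index | best weights kept |

Inputs are standardized with training-split statistics only (leakage
control). Training is bit-deterministic given the seed in
single-threaded BLAS. Two structural checks pin the implementation to
the model class: a depth-0 identity network trained to convergence
(with `restore_best = FALSE`) rank-correlates ≥ 0.99 with the fitted
linear Cox score, and on data with a quadratic log-hazard the network's
validation C-index beats linear Cox by ≥ 0.03.

The fitted score is completed into survival curves by the Breslow
baseline cumulative hazard H₀(t) = Σ_{t_j ≤ t} d_j / Σ_{risk} e^{h(x)},
giving S(t|x) = exp(−H₀(t)·e^{h(x)}). `stratifyRisk` labels a subject
low-risk iff S(3.3 months) > 0.5 — the boundary case is high-risk —
mirroring stratification at the cohort's median PFS.

## 7. Evaluation

* `concordanceIndex` implements C = concordant / evaluable pairs: a
  pair is evaluable iff the times differ and the shorter time carries
  an event; tied risks earn 0.5. It agrees exactly with an O(n²)
  enumeration oracle.
* `timeDependentRoc` uses the cumulative-cases / dynamic-controls
  definition with inverse-probability-of-censoring weights from the
  Kaplan–Meier estimate of the censoring distribution (cases 1/G(T⁻),
  controls 1/G(t)); with no censoring before t it reduces exactly to
  the Mann–Whitney statistic. Sensitivity/specificity are reported at
  the Youden-optimal threshold. The unweighted variant is a switch.
* Kaplan–Meier curves and log-rank tests delegate to the `survival`
  package and are verified against hand product-limit and risk-set
  enumerations.
* `bootstrapCompare` resamples the test split with replacement
  (default 100 replicates), recomputes both models' AUC(t) per
  replicate, and applies a paired t-test per horizon; degenerate
  replicates (no cases or controls) are redrawn and counted.
* `shapleyAttribution` estimates Shapley values by permutation
  sampling against the training-mean background; within every sampled
  ordering the marginal contributions telescope, so efficiency
  (attributions sum to score − baseline) holds exactly.

## 8. The synthetic phantom cohort

`generatePhantom` builds a CT-like volume: a low-intensity lung
ellipsoid in a brighter body, a bright tumor ball with band-limited
texture noise (white noise smoothed at 2 mm, scaled by the
`heterogeneity` parameter), and a binary-branching vessel tree of
bright tubes rasterized around analytic centerlines that stay strictly
inside the lung. Branch centerlines are circular helices with
amplitude a = min(t, 1) mm and pitch b = 3/t mm·rad⁻¹, where t is the
`tortuosity` parameter: a circular helix has constant curvature
a/(a²+b²) and torsion b/(a²+b²), and this coupling makes *both*
increase monotonically with t while keeping the perturbation wavelength
resolvable at branch scale. (Torsion of a helix *falls* with amplitude
at fixed pitch — higher torsion requires a tighter helix, so a pure
"amplitude" parameter cannot produce monotone torsion.) The analytic
centerlines and their closed-form κ/τ ship as ground truth. Defaults
(64³ grid at 1 mm, tumor radius 8 mm, vessel radius 2 mm — typical
calibre for peritumoral vessels at this resolution, 8 branches) are
fixed once; identical specs are bit-identical.

`generateClinicalTable` draws categorical covariates independently from
published cohort marginals (56.8% smokers, 58.7% stage IVB, 71.3%
adenocarcinoma, 98.1% high total protein, 91.3% normal MCV, 31.6%
female; age ~ N(62.2, 9.5)). `generateSurvival` draws event times from
a Weibull proportional-hazards model (default shape 1, scale
3.3/ln 2 months, i.e. baseline median 3.3 months) and independent
uniform-window censoring whose width is calibrated numerically so the
expected censored fraction equals the target (default 30%).
`generateCohort` combines both: per-subject phantom parameters map to
features (tumor volume/diameter, heterogeneity, closed-form branch
torsion/curvature), the default log-hazard loads on tumor volume
(0.55/SD), heterogeneity (0.50/SD), vessel torsion (0.70/SD), normal
total protein (0.70) and high MCV (0.80), and the linear predictor is
recentred so the cohort-level median PFS stays at the baseline median
(covariate dispersion would otherwise drag it down; a constant shift
leaves all hazard ratios untouched). Effect sizes are the generator's
own choices — chosen for realistic moderate discrimination (test
C-index ≈ 0.7), not estimates of any real cohort.

**What the phantoms do not establish.** They share none of real CT's
difficulties: no scanner/protocol variability or beam-hardening, no
respiratory motion, no lesions touching the pleura or mediastinum, no
contrast-phase differences, vessels are homogeneous tubes of a single
radius with a clean intensity contrast, and the clinical covariates are
drawn independently rather than with realistic correlation. Passing
tests therefore demonstrate that the *implementation* recovers known
structure, not that the model transfers to patients.

## 9. Problem sizes and determinism

The test suite and the acceptance script run on deliberately small
instances: 48³–64³ phantoms, cohorts of 120–500, 20 pipeline seeds at
n = 200, 1000 null replicates for screening calibration, brute-force
oracles at n ≤ 50 — sizes at which every oracle is exhaustive and the
whole suite completes in a few minutes on one core. Every stochastic
step takes an explicit seed; the pipeline fans its master seed out to
stage seeds by fixed offsets, and reruns reproduce all artifacts
bit-identically.

## 10. Known limitations

* Mortality is a competing risk for progression and is not modeled.
* The 3D LBP and the exact identities within the 61 + 30 vasculature
  block follow this package's fixed manifests; other toolboxes count
  slightly different members in each family even at identical totals.
* Skeleton-derived torsion remains the noisiest quantity; it is
  reliable as an *ordering* across tortuosity levels (tested), not as
  an unbiased per-branch estimate at low tortuosity.
* The SFS stopping rule (patience 1) can under-select on noisy
  validation splits; the cap and patience are configurable.
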