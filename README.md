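# periSurv

Radiomics and neural Cox survival modeling for predicting
progression-free survival (PFS) after immunotherapy in lung cancer.

Immune checkpoint inhibitors help only a subset of advanced lung-cancer
patients, and the pre-treatment CT already carries prognostic signal:
the texture of the tumor itself, and the geometry of the vasculature
that surrounds it. `periSurv` implements that whole analysis chain as a
tested R package, for imaging scientists and biostatisticians who want
to build or scrutinize such models:

* **Intratumoral radiomics** — after resampling to 1 mm isotropic
  voxels and Z-score intensity standardization, a single-level
  stationary Haar wavelet decomposition produces the eight subbands
  LLL ... HHH; histogram (14), GLCM (22), GLRLM (11) and 3D local
  binary pattern (17) features are computed in the tumor ROI on the
  original volume and every subband, plus 17 mask-only geometry
  features: **9 × 64 + 17 = 593 features**.
* **Peritumoral-vasculature radiomics** — multi-scale Hessian
  (Frangi-type) vesselness, Otsu thresholding, morphological cleanup,
  a peritumoral cube extending 25 mm beyond the tumor bounding box,
  distance-ordered homotopic thinning to centerlines, branch
  partitioning at junctions, and Frenet curvature
  κ = |r′×r″|/|r′|³ and torsion τ = (r′×r″)·r‴/|r′×r″|² per branch:
  **61 morphology + 30 organization = 91 features**, with a 3-SD/20%
  outlier-proportion feature filter.
* **Two-step feature selection** — univariate Cox regression
  (continuous features) and chi-squared tests (categorical clinical
  features) at p < 0.05, then sequential forward selection maximizing
  the validation-split concordance index.
* **Neural Cox survival model** — a multilayer perceptron risk score
  h(x) trained with the Breslow partial-likelihood loss (hazard
  λ(t|x) = λ₀(t)·exp(h(x))), exhaustive hyperparameter grid search with
  a shortest-training-time tie-break, Breslow baseline cumulative
  hazard H₀(t), and personalized PFS curves
  S(t|x) = exp(−H₀(t)·e^{h(x)}). Patients are stratified at the median
  PFS time: low risk ⇔ S(3.3 months) > 50%.
* **Evaluation** — concordance index (concordant / evaluable pairs),
  time-dependent ROC at 1/2/3/6 months with
  inverse-probability-of-censoring weights, Kaplan–Meier curves and
  log-rank tests, 100-replicate bootstrap paired-t AUC comparison of
  nested models, and Monte-Carlo Shapley feature attribution.
* **Synthetic phantom cohort** — since clinical CT cohorts cannot be
  redistributed, a generator builds CT-like volumes (heterogeneous
  tumor, lung, helically perturbed vessel trees with closed-form
  curvature and torsion), clinical tables matching published cohort
  marginals, and Weibull proportional-hazards outcomes with known
  coefficients, so every stage of the pipeline is testable against
  ground truth.

## Worked example

```r
library(periSurv)

# a 206-subject synthetic cohort with known hazard structure
coh <- generateCohort(206, seed = 11)
res <- runPipeline(coh$features, coh$outcome, seed = 11)

res$selection$selected
#> [1] "vessel_mean_curvature" "tumor_volume_cm3"
round(res$test$cindex, 3)
#> [1] 0.708
round(sapply(res$test$roc, function(r) r$auc), 3)
#>    t1    t2    t3    t6
#> 0.756 0.751 0.748 0.745
table(res$test$stratification)
#>  low high
#>   31   31
signif(res$test$log_rank$p, 3)
#> [1] 6.75e-07
```

The pipeline split the cohort 55/15/30, screened the feature table at
p < 0.05 on the training split, greedily selected vessel curvature and
tumor volume (two of the planted hazard drivers), trained the neural
Cox model, and on the held-out test third achieved a concordance of
0.71 with AUCs near 0.75 at every horizon; the 3.3-month/50% risk
stratification separates the test Kaplan–Meier curves decisively
(log-rank p ≈ 7 × 10⁻⁷).

Image-level extraction works the same way on any NIfTI volume + tumor
mask:

```r
ph  <- generatePhantom(phantomSpec(seed = 17))
vol <- zscoreStandardize(resampleIsotropic(ph$volume))
it  <- extractIntratumoral(vol, ph$tumor)      # 593 named features
vs  <- extractVesselRadiomics(vol, ph$tumor, lung_mask = ph$lung)  # 91
```

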