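# cfodts — Collagen Fiber Orientation Disorder in Tumor-associated Stroma

`cfodts` is an R package for quantifying how *disordered* the collagen
fibers in tumor-associated stroma are, directly from routine H&E-style RGB
histology images, and for turning that measurement into a prognostic risk
model of disease-free survival (DFS). In invasive breast carcinoma, stromal
collagen that is highly *aligned* (low disorder) accompanies invasion and
worse outcome; stroma whose fibers point every which way (high disorder)
accompanies better outcome. The package measures that contrast without any
special stain or second-harmonic imaging — only the H&E image.

## The measurement

1. **Tissue masks.** Epithelium and stroma are separated (by stain
   deconvolution, or by supplying your own masks); epithelial patches are
   merged into a tumor mask by dilation and hole filling; the *leading
   edge* is the band of tumor within 500 µm of its boundary.
2. **Fiber detection.** A derivative-of-Gaussian filter jet at one scale
   feeds a seven-class Basic Image Feature classifier (flat, slope,
   dark/light blob, dark/light line, saddle). Collagen fibers are locally
   dark ridges, so connected *dark line* pixels inside tumor-associated
   stroma become fiber segments; each segment's orientation Θ ∈ [0°, 180°)
   is the major axis of its second-moment ellipse.
3. **Disorder entropy (CFOD-TS).** Within each square tumor neighborhood
   (field of view, FOV), orientations are discretized into 18 bins of 10°
   and every pair of fibers increments an 18 × 18 orientation co-occurrence
   matrix C. The disorder value is the Shannon entropy
   H = −Σᵢⱼ Pᵢⱼ log₂ Pᵢⱼ of P = C / ΣC, in bits. Neighborhoods with too
   little stroma or too few fibers are discarded.
4. **Patient features.** Nine FOVs (50–250 µm in steps of 25) × two regions
   (leading edge, whole tumor) give an 18-feature patient vector, each
   entry the mean entropy over valid neighborhoods.
5. **Risk model.** A LASSO-penalized Cox model with the feature budget
   fixed at ≈10% of the training cohort size (k = round(0.1 n)) selects the
   features; the risk score is their coefficient-weighted sum, dichotomized
   at the threshold whose log-rank split of the training set is most
   significant. Kaplan–Meier curves, log-rank tests, hazard ratios,
   uni/multivariate Cox tables, Wilcoxon group comparisons and TAILORx
   Oncotype DX categories round out the reporting.

A synthetic-data module generates fibrous-stroma phantoms with known
orientation concentration (axial von Mises κ) around epithelial blobs, and
survival cohorts with the feature structure the extractor produces, so the
entire pipeline is testable end to end without slide archives.

## Worked example

```r
library(cfodts)

# A 0.64 mm^2 phantom: strongly aligned fibers (kappa = 8) in a 150 um
# leading-edge band, disordered fibers (kappa = 0.5) in the core.
ph <- generate_wsi_phantom(core_kappa = 0.5, edge_kappa = 8,
        tumor_geometry = list(center_um = c(400, 400), radius_um = 350),
        seed = 42, tile_um = 800, band_um = 150)
fv <- patient_feature_vector(ph$tile, ph$masks)
round(fv[c("CFOD_edge_50", "CFOD_whole_50",
           "CFOD_edge_100", "CFOD_whole_100")], 2)
#>  CFOD_edge_50  CFOD_whole_50  CFOD_edge_100 CFOD_whole_100
#>          3.37           4.46           4.11           4.88
```

The aligned leading edge measures about one bit *less* disordered than the
whole tumor at matched FOV — the direction that marks aggressive disease.

```r
# Simulated 78-patient cohort in which low disorder drives hazard
coh <- generate_survival_cohort(cohort_spec(n_patients = 78, seed = 1))
fit <- cfod_cox(coh$features, coh$survival)   # k = round(0.1 * 78) = 8
fit
#> CFOD-TS LASSO-Cox risk model: 8 of 18 features (n = 78)
#>   CFOD_edge_50  CFOD_edge_100  CFOD_whole_75 CFOD_whole_125 CFOD_whole_150
#>        -0.0102        -0.0529        -0.3446        -0.1803        -0.1479
#> CFOD_whole_200 CFOD_whole_225 CFOD_whole_250
#>        -0.1766        -0.2183        -0.1523
#> risk threshold 0.2147 (training log-rank p = 5.62e-12)

grp <- predict(fit, coh$features, type = "group")
km_logrank(grp, coh$survival$time_days, coh$survival$event)
#> Risk stratification: HR = 7.98 (95% CI 4.03-15.80), log-rank p = 5.62e-12
#>   low risk: n = 51 (32 events); high risk: n = 27 (25 events)
```

All eight selected coefficients are negative: lower disorder raises the
risk score, and the high-risk group recurs sooner. (The training-set
log-rank p is anti-conservative because the threshold is optimized on the
same data; validate on held-out cohorts with `run_validate()`, which never
refits.)

A command-line front end (`inst/cli/cfodts.R`) exposes the same pipeline as
`simulate` / `extract` / `model` / `validate` subcommands.

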