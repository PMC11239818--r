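# DeltaRadiomics

Longitudinal multiparametric-MRI delta radiomics for early prediction of
pathologic complete response (pCR) in triple-negative breast cancer
treated with neoadjuvant systemic therapy (NAST).

Patients imaged at baseline (BL) and after 2 (C2) and 4 (C4) treatment
cycles contribute dynamic contrast-enhanced (DCE) early-subtraction and
diffusion-weighted (DWI, b = 800) volumes. The package implements the
whole analysis chain:

* **Segmentation** — refinement of a rough contour into the analysis VOI
  by exact Otsu histogram thresholding (fixed-quantile alternative),
  necrosis/clip exclusion, index-lesion selection, tumor-bed fallback.
* **Radiomics** — per VOI and sequence, 10 first-order features
  (min, max, mean, sd, skewness, Fisher kurtosis, p1/p5/p95/p99) and
  300 gray-level co-occurrence (GLCM) features: 25 Haralick-style
  statistics × distances {1,2,3} × 4 in-plane directions, on a 32-level
  VOI-relative quantization — 310 features per (VOI, sequence).
* **Delta radiomics** — absolute (AD = late − early) and relative
  (RD = (late − early)/|early|) differences over C2/BL, C4/BL, C4/C2,
  stacked with the raw timepoints into a 310 × 18-block
  `SummarizedExperiment` per cohort.
* **Screening** — univariate Mann–Whitney AUC (oriented
  max(AUC, 1 − AUC)) with the rank-sum p-value; a feature passes at
  AUC ≥ 0.7 in both the training and testing sets with p < 0.001.
* **Modeling** — elastic-net logistic regression (α grid 0.1–1.0,
  100-value λ path, winner by fivefold CV AUC) on a stratified 2:1
  split (78/85 strata map exactly to 109 = 52 + 57 train and
  54 = 26 + 28 test), DeLong CIs and p-values, pooled 3-fold-CV and
  linear/RBF SVM comparators, and an explicit serializable model grid.
* **Reader agreement** — per-feature Pearson r, Wilcoxon signed-rank p,
  and inter-/intrareader variance ratios from a one-way
  method-of-moments decomposition over repeat contours.
* **Synthetic cohort generator** — a fully seeded simulator (ellipsoidal
  tumors, spatially correlated interior texture, mono-exponential DWI
  with ADC computed from the b = 100/800 pair, two readers with repeat
  contours) producing NIfTI volumes, masks and a clinical table, so the
  pipeline runs end-to-end with no external data. Response is planted as
  label-dependent shrinkage and texture homogenization; baseline
  characteristics carry no label signal, so early-change (delta) models
  must genuinely recover the effect to beat baseline-only models.

## Worked example

```r
library(DeltaRadiomics)

cfg <- cohortConfig(nPatients = 40, timepoints = c("BL", "C2"), seed = 7)
clinical <- generateCohort(cfg)
table(clinical$pcr)
#>  0  1
#> 21 19

ext <- extractCohortFeatures(cfg, clinical = clinical)  # simulate + segment + extract
ext$se
#> class: SummarizedExperiment
#> dim: 2480 40
#> assays(1): features
#> rowData names(3): sequence block feature

sp <- stratifiedSplit(clinical$pcr, seed = 7)   # 27 train / 13 test
m <- fitModelSpec(ext$se, sp,
                  list(family = "RD_C2_BL", sequences = c("DCE", "DWI"),
                       learner = "elastic_net_logistic", cvFoldsHyper = 5L),
                  seed = 7)
m
#> ModelResult [RD_C2_BL]
#>   18 selected features; AUC train 1.000 / test 1.000 (CI 1.000-1.000),
#>   acc 0.923, p 0
head(m@selectedFeatures, 3)
#> "DCE.RD_C2_BL.fo_sd"
#> "DCE.RD_C2_BL.glcm_joint_entropy_d1_a10"
#> "DCE.RD_C2_BL.glcm_contrast_d1_a11"
```

The relative-change (RD, C2/BL) model separates the synthetic cohort
almost perfectly because the planted effect — responders' tumors shrink
and homogenize faster between BL and C2 — lives exactly in those
features (the elastic net picks the texture-s.d. and entropy/contrast
changes); the same model family restricted to baseline features alone
hovers at chance, since baseline size and heterogeneity are
label-independent by construction.

`runPipeline(pipelineConfig(...))` chains all stages (screening, full
model grid, agreement, clinical table, manifest with checksums), and
`inst/scripts/delta-radiomics.R` exposes the stages as shell
subcommands (`simulate`, `extract`, `screen`, `fit`, `cv`, `agree`,
`table1`, `run`).

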