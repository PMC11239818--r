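---
title: "Longitudinal multiparametric-MRI delta radiomics: models and methods"
author: "DeltaRadiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal multiparametric-MRI delta radiomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Triple-negative breast cancer (TNBC) treated with neoadjuvant systemic
therapy (NAST) has a sharply better prognosis when surgery reveals a
pathologic complete response (pCR). An imaging biomarker that predicts pCR
*early* in the treatment course — after two or four cycles rather than at
surgery — would let responders continue or de-escalate and non-responders
switch therapy. This package implements a longitudinal radiomics pipeline
for that problem: tumors are segmented on dynamic contrast-enhanced (DCE)
early-subtraction MRI and b = 800 diffusion-weighted imaging (DWI) at
baseline (BL) and after 2 (C2) and 4 (C4) cycles; first-order and
gray-level co-occurrence matrix (GLCM) texture features are extracted per
volume of interest (VOI); between-timepoint *delta* features (absolute and
relative differences) are formed; features are screened univariately by
AUC; and multivariate elastic-net logistic regression models over feature
families are trained on a stratified 2:1 split and evaluated on the
holdout, with SVM and 3-fold-CV comparators and an inter-/intrareader
reproducibility analysis.

Because no image data are publicly deposited for this design, the package
ships a first-class synthetic cohort generator that reproduces the
statistical structure the analysis assumes, so every downstream stage is
exercised end-to-end without any download.

# The synthetic cohort: what it emulates and what it does not

`cohortConfig()` / `generateCohort()` / `simulateStudy()` produce a cohort
of (by default) 163 patients with 78 (48%) pCR, each with DCE
early-subtraction, DWI b = 100 / b = 800, and derived ADC volumes at BL,
C2, C4 on a 32 x 32 x 16 grid with 1.5 x 1.5 x 3 mm voxels (in-plane
resolution finer than slice thickness, as in typical breast protocols).

The tumor model is deliberately minimal:

* **Geometry** — an ellipsoid with in-plane semi-axis ~ U(7, 12) mm,
  mildly anisotropic (axis ratios U(0.7, 1)), jittered center. Its volume
  is multiplied per cycle-pair by a label-specific shrink factor
  (default 0.55 for pCR, 0.85 for non-pCR, each with per-patient Gaussian
  jitter of sd 0.04). When the tumor vanishes the generator emits a fixed
  4 mm "tumor bed" mask at the prior centroid, mirroring clinical
  tumor-bed contouring, and flags the study.
* **Texture** — interior enhancement is 1 + sd_t x (Gaussian-smoothed
  white noise, correlation length ~2 mm in-plane), where the texture
  s.d. starts at U(0.25, 0.45) and is multiplied per cycle-pair by a
  label-specific homogenize factor (default 0.60 pCR / 0.92 non-pCR).
  This encodes the premise that response reduces enhancement
  heterogeneity. Baseline size and heterogeneity are label-independent,
  so baseline-only models carry no signal by construction — the
  qualitative pattern this design targets (early-change models beat
  baseline models) is a *planted* property the pipeline must recover,
  not an artifact of the test.
* **DWI / ADC** — signal follows a mono-exponential decay
  S(b) = S0 exp(-b ADC) over a smoothly varying diffusivity field
  (~0.7-1.1 x 10^-3 mm^2/s in tumor, 2 x 10^-3 in background), and the
  study's ADC map is *computed* from the simulated b = 100/800 pair via
  `computeADC()`, never copied from the latent field.
* **Necrosis** — with probability 0.15 a low-signal core (35% of the
  semi-axes) is embedded and its mask exposed, to exercise exclusion.
* **Readers** — `simulateReaderMasks()` softens the truth mask with a
  Gaussian kernel and re-thresholds after adding smooth perturbation
  fields: one per reader (inter-reader scale) plus one per repeat
  (intra-reader scale), so between-reader displacement dominates
  within-reader displacement by construction, and Dice overlap with truth
  decreases in the jitter scale.

Not emulated: pulse-sequence physics, pharmacokinetics, bias fields,
motion, rib/heart anatomy, non-ellipsoidal shapes, or any correlation of
clinical covariates with outcome (covariates are drawn from realistic
marginal frequencies only, to exercise the cohort-comparison stage).
Passing tests therefore demonstrate the *pipeline's* correctness and the
qualitative recoverability of a planted longitudinal effect — not
clinical performance on real images.

**Determinism.** All randomness derives from one integer seed through a
stable 31-adic string hash per patient/timepoint/purpose, so the same
config is bitwise reproducible and extending the cohort does not reshuffle
existing patients. Smooth fields are generated on the padded tumor
bounding box (the background is flat noise), which is both faster and
prevents spurious far-field contour islands.

# Segmentation

Clinical practice refines a generous hand contour semi-automatically by
histogram thresholding. `thresholdSegment()` implements Otsu's criterion
computed *exactly* over the empirical intensity distribution inside the
rough contour (every cut between consecutive distinct values is scored by
between-class variance), with a fixed-quantile alternative. Voxels at or
above threshold are kept, and 26-connected components smaller than
`minComponentVoxels` (default 5) are removed as speckle. Degenerate cases
are defined behavior: a constant-intensity contour is returned unchanged;
if nothing survives, the empty VOI carries the tumor-bed flag so features
are still computed over the contoured bed. The operation is idempotent
when re-applied with the threshold it reports (`attr(voi, "threshold")`);
re-computing the threshold on its own output would legitimately tighten
it, which is why the invariant is stated "with the same threshold".
Necrosis/clip exclusion is plain mask algebra (`excludeRegions()`), and
`selectIndexLesion()` takes the largest candidate by physical volume with
a lexicographic-centroid tie-break.

# Radiomic features

Each (study, VOI, sequence) yields exactly 310 features: DCE uses the
early-subtraction volume, DWI the b = 800 volume.

**First-order (10).** minimum, maximum, mean, sd (n-1), skewness
(standardized third moment), kurtosis (Fisher excess — a normal sample
scores 0; the convention matters because delta features change sign
structure under the Pearson convention), and the 1st/5th/95th/99th
percentiles with linear interpolation between order statistics. Constant
input gives sd 0 and skewness/kurtosis 0 by convention; an empty VOI
yields an all-missing vector, never an error.

**GLCM (300 = 25 statistics x 3 distances x 4 directions).** Intensities
are quantized to 32 equal-width bins over the VOI min-max (the common
radiomics default; quantization is therefore invariant to intensity
shifts and rescaling). Co-occurrence is accumulated per axial slice at
distances {1, 2, 3} along the four in-plane directions (1,0), (0,1),
(1,1), (1,-1) — 2D in-plane by default because slice thickness (3 mm)
is twice the in-plane spacing; both pair members must lie inside the
VOI; matrices are symmetrized and normalized to sum 1. Each offset is
reported separately (not averaged): with a standard 25-statistic set that
is the only decomposition yielding exactly 300. The 25 statistics
(autocorrelation, joint average, cluster prominence/shade/tendency,
contrast, correlation, difference average/entropy/variance, joint
energy/entropy, IMC1, IMC2, IDM, IDMN, ID, IDN, inverse variance,
maximum probability, sum average/entropy, sum of squares, dissimilarity,
homogeneity) use textbook formulas with base-2 logarithms. Two standard
identities are used for the information measures (HXY1 = HXY2 = HX + HY
for the cross entropies); the test suite checks every statistic at every
offset against a literal pair-enumeration oracle to 1e-10. Degenerate
matrices take analytic limits (correlation of a single-level matrix is 1
by convention); an offset with no valid pairs yields missing statistics.
Note two pairs in the configured list are algebraic duplicates
(dissimilarity = difference average, homogeneity = ID); they are kept as
named because the feature count contract is defined over the named list.

# Delta features

`absoluteDifference()` is late - early per feature;
`relativeDifference()` is (late - early) / |early|, which preserves the
sign of the change for negative-valued features and is invariant to
rescaling both timepoints. "C2/BL" notation is read as "change between C2
and BL", not a ratio. Early values within 1e-12 of zero yield missing
(not infinite) deltas; missingness always propagates feature-wise, never
patient-wise. With 3 timepoints, 3 ordered pairs x {AD, RD}, and 2
sequences, `assembleFeatureTable()` stacks 310 x 18 = 5580 rows per
patient into a `SummarizedExperiment` whose rowData carries
(sequence, block, feature) and whose colData is the clinical table.

# Screening and modeling

`featureAUC()` computes the Mann-Whitney AUC from ranks (ties half),
oriented as max(AUC, 1 - AUC) because discrimination is direction-free at
screening time, with the two-sided normal-approximated rank-sum p-value
(the test canonically paired with AUC). `screenFeatures()` passes a
feature when AUC >= 0.7 in *both* the training and testing sets and
p < 0.001.

`stratifiedSplit()` rounds the per-stratum training count to the nearest
integer with halves up — the one convention that maps 78/85 strata at 2:1
to the 52 + 57 = 109 / 26 + 28 = 54 split.

`fitElasticNet()` grids the mixing parameter alpha over {0.1, ..., 1.0}
and a 100-value lambda path, picking the pair maximizing mean fivefold
CV AUC (folds stratified by label and shared across alphas; features
standardized internally on training statistics; constant features dropped
with a warning). Numerical choices: glmnet's coordinate-descent tolerance
is set to 1e-5 (selection and CV AUC are indistinguishable from 1e-7 at
n ~ 100, p ~ 600, at a ~2.5x speedup); when folds are too small for an
AUC criterion glmnet falls back to deviance and the selection criterion is
re-oriented accordingly. `evaluateHoldout()` reports training/test AUC
(as-is, not reoriented), accuracy at probability 0.5, a DeLong 95% CI,
and a DeLong-variance p-value against AUC = 0.5. `crossValidate()` gives
the pooled out-of-fold AUC over unstratified seed-controlled folds,
refolding (with a message) if a fold leaves single-class training data.
`fitSVM()` is the comparator (linear/RBF), cost tuned over {0.1, 1, 10}
by the same 5-fold CV-AUC protocol, probabilities exposed for ROC.
`enumerateModelGrid()` makes the model grid explicit and serializable: one
model per feature family (each timepoint, each delta block; DCE + DWI
combined) plus configured combinations, the late-timepoint +
absolute-change pairing included by default.

# Reader agreement

`agreementReport()` combines, per feature: Pearson correlation between
the two readers' first contours; the two-sided Wilcoxon signed-rank test
(zero differences dropped; exact where available; all-zero differences
give p = 1 by convention); and the inter-/intrareader variance ratio.
The ratio uses a one-way method-of-moments decomposition per patient —
intra = mean within-reader repeat variance, inter = variance of reader
means minus intra/K floored at zero — then ratios the across-patient
means. Ratios are reported rounded to 4 decimals. With only two readers
the floored between-reader component is upward-biased under equal
variance components; the test suite's oracle is therefore a Monte-Carlo
of the estimator itself rather than the naive component ratio. Clinical
reader studies rarely report how intrareader variance is obtained;
explicit repeat contours (provided by the simulator) are this package's
documented choice. Agreement runs on DCE features by default.

# Pipeline, formats, reproducibility

`runPipeline()` executes: cohort -> simulate/segment/extract -> delta
table -> stratified split -> univariate screening -> model grid
(optional 3-fold CV comparison) -> reader agreement -> clinical
comparison table -> manifest. Volumes and masks are NIfTI-1 (RNifti),
tables CSV, configs/manifests JSON; the manifest records package version,
seed, config hash, stage list and md5 checksums of every output. The
clinical comparison uses the Wilcoxon rank-sum test for continuous and
Fisher's exact test for categorical variables (Monte-Carlo fallback,
seed-controlled, for tables where the exact computation fails; a
single-level variable reports NA).

# Problem sizes used by the test suite and acceptance script

The shipped checks use: one 163-patient cohort at 32 x 32 x 16 voxels
with timepoints BL + C2 for each of the recovery and null-control
experiments, analyzed under 20 independent split/model seeds (10 seeds
for the CV-vs-holdout comparison); a full three-timepoint 163-patient
run for screening; and a 25-patient BL cohort with 2 readers x 2 repeats
for agreement, re-contoured under 10 seeds. Cohort-regeneration
robustness is exercised separately by the generator's property tests.
These sizes are the package's desk-scale study conditions; the generator
scales to larger grids and cohorts through `cohortConfig()`.

# Known limitations

* The synthetic effect sizes are strong by design (planted-signal
  recovery); absolute AUCs on synthetic cohorts are not comparable to
  clinical AUCs on real images.
* 2D in-plane co-occurrence is the default; a 13-direction 3D mode is a
  natural extension but is not implemented.
* The agreement module reports the variance-ratio family the design
  calls for, not ICC variants or Bland-Altman analyses.
* DWI VOIs reuse the DCE-refined contour rather than an independent DWI
  contour; on the simulator both sequences share the truth geometry, so
  nothing is lost, but real-data use would want a per-sequence contour.
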