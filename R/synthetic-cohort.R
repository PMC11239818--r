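#' Response-effect parameters for the synthetic cohort
#'
#' Encodes the biological premise the analysis rests on: tumors of patients
#' who go on to pathologic complete response (pCR) shrink and homogenize
#' (lose enhancement heterogeneity) faster across treatment cycles than
#' non-pCR tumors. Factors are per cycle-pair (BL to C2, C2 to C4) and
#' multiplicative.
#'
#' @param volumeShrinkPcr,volumeShrinkNonPcr Tumor volume multiplier per
#'   cycle pair, in (0, 1]; the pCR factor must not exceed the non-pCR one.
#' @param textureHomogenizePcr,textureHomogenizeNonPcr Multiplier applied
#'   per cycle pair to the s.d. of the interior texture field.
#' @param noiseSd Additive white-noise s.d., in units of the mean tumor
#'   enhancement (which is 1).
#' @param necrosisProb Probability that a tumor carries a necrotic core.
#' @return A validated list of class `ResponseEffect`.
#' @export
responseEffect <- function(volumeShrinkPcr = 0.55, volumeShrinkNonPcr = 0.85,
                           textureHomogenizePcr = 0.60,
                           textureHomogenizeNonPcr = 0.92,
                           noiseSd = 0.05, necrosisProb = 0.15) {
  e <- list(volumeShrinkPcr = volumeShrinkPcr,
            volumeShrinkNonPcr = volumeShrinkNonPcr,
            textureHomogenizePcr = textureHomogenizePcr,
            textureHomogenizeNonPcr = textureHomogenizeNonPcr,
            noiseSd = noiseSd, necrosisProb = necrosisProb)
  stopifnot(volumeShrinkPcr >= 0, volumeShrinkPcr <= 1,
            volumeShrinkNonPcr > 0, volumeShrinkNonPcr <= 1,
            textureHomogenizePcr > 0, textureHomogenizeNonPcr > 0,
            noiseSd >= 0, necrosisProb >= 0, necrosisProb <= 1)
  if (volumeShrinkPcr > volumeShrinkNonPcr ||
      textureHomogenizePcr > textureHomogenizeNonPcr)
    stop("responders must shrink/homogenize at least as much as non-responders")
  structure(e, class = "ResponseEffect")
}

#' Synthetic cohort configuration
#'
#' Defaults reproduce the study conditions the analysis is designed for:
#' 163 patients of whom 78 (48%) reach pCR, imaged at baseline and after 2
#' and 4 cycles of neoadjuvant systemic therapy.
#'
#' @param nPatients Cohort size (>= 2).
#' @param pcrFraction Fraction of pCR patients, in (0, 1); the pCR count is
#'   `round(nPatients * pcrFraction)` exactly.
#' @param timepoints Ordered subset of `c("BL", "C2", "C4")`.
#' @param gridShape Voxels per axis (each >= 16).
#' @param voxelSpacing mm per axis.
#' @param effect A [responseEffect()].
#' @param seed Global integer seed; all per-patient randomness is derived
#'   from it through stable hashing, so extending the cohort does not
#'   reshuffle existing patients.
#' @return A validated list of class `CohortConfig`.
#' @export
cohortConfig <- function(nPatients = 163, pcrFraction = 78 / 163,
                         timepoints = c("BL", "C2", "C4"),
                         gridShape = c(32, 32, 16),
                         voxelSpacing = c(1.5, 1.5, 3),
                         effect = responseEffect(), seed = 1L) {
  if (nPatients < 2) stop("nPatients must be >= 2")
  if (pcrFraction <= 0 || pcrFraction >= 1)
    stop("pcrFraction must lie strictly inside (0, 1)")
  if (any(gridShape < 16)) stop("gridShape must be >= 16 voxels per axis")
  timepoints <- match.arg(timepoints, c("BL", "C2", "C4"), several.ok = TRUE)
  stopifnot(inherits(effect, "ResponseEffect"))
  structure(list(nPatients = as.integer(nPatients), pcrFraction = pcrFraction,
                 timepoints = timepoints, gridShape = as.integer(gridShape),
                 voxelSpacing = as.numeric(voxelSpacing), effect = effect,
                 seed = as.integer(seed)),
            class = "CohortConfig")
}

## Table-1-style marginal frequencies for clinical covariates. Sampled
## independently of the outcome label: they exist to exercise the cohort
## comparison machinery, not to carry signal.
.clinicalMarginals <- list(
  histology = c("Invasive ductal carcinoma" = 146, "Metaplastic" = 11,
                "Invasive mammary carcinoma" = 3,
                "Poorly differentiated carcinoma" = 2, "Apocrine" = 1),
  clinical_stage = c(I = 22, II = 114, III = 27),
  t_category = c(T1 = 31, T2 = 112, T3 = 18, T4 = 2),
  n_category = c(N0 = 108, N1 = 36, N2 = 7, N3 = 12),
  surgery = c("Breast-conserving surgery" = 96, "Total mastectomy" = 67)
)

#' Generate a synthetic patient cohort
#'
#' Draws patient records (pCR label plus clinical covariates with realistic
#' marginal frequencies). Exactly `round(nPatients * pcrFraction)` patients
#' are labeled pCR; which patients carry the label is randomized under the
#' config seed.
#'
#' @param config A [cohortConfig()].
#' @return A `data.frame` with one row per patient: `patient_id`, `pcr`
#'   (1 = pCR), `age`, `clinical_stage`, `t_category`, `n_category`,
#'   `histology`, `surgery`.
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  n <- config$nPatients
  nPcr <- round(n * config$pcrFraction)
  if (nPcr < 1 || nPcr > n - 1)
    stop("pcrFraction leaves one class empty at this cohort size")
  ids <- sprintf("P%04d", seq_len(n))
  labels <- withSeed(stableHash(config$seed, "labels"), {
    lab <- integer(n)
    lab[sample.int(n, nPcr)] <- 1L
    lab
  })
  covars <- lapply(ids, function(id) {
    withSeed(stableHash(config$seed, id, "clinical"), {
      draw <- function(freq) sample(names(freq), 1L, prob = freq)
      data.frame(
        age = max(23, min(78, round(rnorm(1, 49, 10)))),
        clinical_stage = draw(.clinicalMarginals$clinical_stage),
        t_category = draw(.clinicalMarginals$t_category),
        n_category = draw(.clinicalMarginals$n_category),
        histology = draw(.clinicalMarginals$histology),
        surgery = draw(.clinicalMarginals$surgery),
        stringsAsFactors = FALSE)
    })
  })
  out <- cbind(data.frame(patient_id = ids, pcr = labels,
                          stringsAsFactors = FALSE),
               do.call(rbind, covars))
  rownames(out) <- NULL
  out
}

## Per-patient latent parameters, independent of timepoint (and of label
## except through the effect factors), reproducibly derived from the seed.
patientParams <- function(patientRecord, config) {
  eff <- config$effect
  pcr <- patientRecord$pcr == 1L
  withSeed(stableHash(config$seed, patientRecord$patient_id, "tumor"), {
    shrink <- if (pcr) eff$volumeShrinkPcr else eff$volumeShrinkNonPcr
    homog  <- if (pcr) eff$textureHomogenizePcr else eff$textureHomogenizeNonPcr
    js <- rnorm(1, 0, 0.04); jh <- rnorm(1, 0, 0.04)
    list(
      r0 = runif(1, 7, 12),                     # mm, in-plane semi-axis
      axisRatio = runif(2, 0.7, 1.0),           # y/x and z/x semi-axis ratios
      center = runif(3, -2, 2),                 # mm offset from grid center
      tex0 = runif(1, 0.25, 0.45),              # baseline texture s.d.
      adc0 = runif(1, 7e-4, 1.1e-3),            # mm^2/s at baseline
      necrosis = runif(1) < eff$necrosisProb,
      shrink = if (shrink == 0) 0 else min(1, max(0.05, shrink + js)),
      homog  = min(1.2, max(0.02, homog + jh)))
  })
}

ellipsoidMask <- function(gridShape, voxelSpacing, center, semi) {
  if (any(semi <= 0)) return(array(FALSE, dim = gridShape))
  ax <- lapply(1:3, function(k)
    ((seq_len(gridShape[k]) - (gridShape[k] + 1) / 2) * voxelSpacing[k] -
       center[k]) / semi[k])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  array(d2 <= 1, dim = gridShape)
}

#' Simulate one patient-timepoint MRI study
#'
#' Builds an ellipsoidal tumor whose volume and interior texture
#' heterogeneity decay across BL, C2, C4 according to the patient's
#' label-specific response factors. The tumor interior is a spatially
#' correlated Gaussian texture on a quiet background; DWI volumes follow a
#' mono-exponential signal decay over a smoothly varying diffusivity field,
#' and the returned ADC map is computed from the simulated DWI pair via
#' [computeADC()]. The truth mask (and necrotic-core mask, when present) is
#' stored in the study `metadata`.
#'
#' @param patientRecord One row of [generateCohort()] output (or a list with
#'   `patient_id` and `pcr`).
#' @param timepoint One of the config timepoints.
#' @param config A [cohortConfig()].
#' @return An [MRIStudy-class]; `metadata(study)$truthMask` is a
#'   [VOIMask-class], `metadata$tumorBed` flags vanished tumors.
#' @export
simulateStudy <- function(patientRecord, timepoint, config) {
  stopifnot(inherits(config, "CohortConfig"))
  if (!timepoint %in% config$timepoints)
    stop("timepoint not in config$timepoints")
  pp <- patientParams(patientRecord, config)
  eff <- config$effect
  gs <- config$gridShape; vs <- config$voxelSpacing
  tIndex <- match(timepoint, c("BL", "C2", "C4")) - 1L
  volFac <- pp$shrink^tIndex
  rScale <- volFac^(1 / 3)
  semi <- pp$r0 * c(1, pp$axisRatio) * rScale
  texSd <- pp$tex0 * pp$homog^tIndex
  adcT <- pp$adc0 * (1 + 0.15 * tIndex * (1 - pp$shrink))

  mask <- ellipsoidMask(gs, vs, pp$center, semi)
  tumorBed <- !any(mask)
  if (tumorBed) {
    ## tumor no longer visible: contour a small fixed-radius bed at the
    ## prior tumor centroid so features are still computed over the bed
    mask <- ellipsoidMask(gs, vs, pp$center, 4 * c(1, pp$axisRatio))
  }
  necMask <- array(FALSE, dim = gs)
  if (pp$necrosis && !tumorBed)
    necMask <- ellipsoidMask(gs, vs, pp$center, semi * 0.35)

  ## spatially correlated fields are only consumed inside the tumor (the
  ## background is flat noise), so generate them on the padded bounding box
  bb <- expandBbox(maskBbox(mask | necMask, gs), 3L, gs)
  ds <- lengths(bb)

  withSeed(stableHash(config$seed, patientRecord$patient_id, timepoint, "img"), {
    tex <- array(0, dim = gs)
    tex[bb[[1]], bb[[2]], bb[[3]]] <- smoothNoiseField(ds, c(1.2, 1.2, 0.6))
    texDwi <- array(0, dim = gs)
    texDwi[bb[[1]], bb[[2]], bb[[3]]] <- smoothNoiseField(ds, c(1.2, 1.2, 0.6))
    adcField <- array(2e-3, dim = gs)
    adcField[bb[[1]], bb[[2]], bb[[3]]] <-
      pmax(adcT + 1.5e-4 * smoothNoiseField(ds, c(2, 2, 1)), 1e-5)

    dce <- array(rnorm(prod(gs), 0.05, eff$noiseSd), dim = gs)
    dce[mask] <- 1 + texSd * tex[mask] + rnorm(sum(mask), 0, eff$noiseSd)
    dce[necMask] <- 0.1 + rnorm(sum(necMask), 0, eff$noiseSd)

    s0 <- array(0.3, dim = gs)
    s0[mask] <- 2 + 2 * texSd * texDwi[mask]
    adcField[!mask] <- 2e-3
    b100 <- pmax(s0 * exp(-100 * adcField) +
                   rnorm(prod(gs), 0, eff$noiseSd * 0.05), 1e-6)
    b800 <- pmax(s0 * exp(-800 * adcField) +
                   rnorm(prod(gs), 0, eff$noiseSd * 0.05), 1e-6)
    adc <- computeADC(b100, b800, 100, 800)

    truth <- VOIMask(mask, patientId = patientRecord$patient_id,
                     timepoint = timepoint, readerId = "truth",
                     tumorBed = tumorBed)
    MRIStudy(patientRecord$patient_id, timepoint,
             dceSubtraction = dce, dwiB100 = b100, dwiB800 = b800, adc = adc,
             voxelSpacing = vs,
             metadata = list(truthMask = truth, necrosisMask = necMask,
                             tumorBed = tumorBed, textureSd = texSd,
                             semiAxes = semi))
  })
}

#' Apparent diffusion coefficient from a DWI pair
#'
#' Mono-exponential model: `ADC = ln(sLow / sHigh) / (bHigh - bLow)`,
#' voxelwise. Voxels where either signal is non-positive (or non-finite)
#' are masked as `NA` rather than raising an error.
#'
#' @param sLow,sHigh Arrays of DWI signal at the low/high b-value.
#' @param bLow,bHigh b-values in s/mm^2, `bHigh > bLow >= 0`.
#' @return Array of ADC values in mm^2/s, `NA` where undefined.
#' @export
computeADC <- function(sLow, sHigh, bLow, bHigh) {
  if (bHigh <= bLow) stop("bHigh must exceed bLow")
  if (bLow < 0) stop("b-values must be non-negative")
  stopifnot(identical(dim(sLow), dim(sHigh)))
  bad <- !is.finite(sLow) | !is.finite(sHigh) | sLow <= 0 | sHigh <= 0
  adc <- log(sLow / sHigh) / (bHigh - bLow)
  adc[bad] <- NA_real_
  adc
}

#' Simulate reader contours around a truth mask
#'
#' Emulates two-reader semi-automatic contouring with repeat contours per
#' reader. The truth mask is softened with a Gaussian kernel and re-thresholded
#' after adding a smooth random boundary-perturbation field: one field per
#' reader (scale = inter-reader jitter) plus one per repeat (scale =
#' intra-reader jitter), so between-reader displacement is at least as large
#' as within-reader displacement by construction. `jitter = 0` returns exact
#' copies of the truth.
#'
#' @param trueMask A [VOIMask-class]; must be nonempty unless tumor-bed
#'   flagged.
#' @param jitter Either one number (inter-reader scale; intra defaults to
#'   half of it) or `c(inter, intra)` with `inter >= intra`. Dimensionless;
#'   boundary displacement grows with it.
#' @param nReaders,nRepeats Number of simulated readers and repeats each.
#' @param seed Integer seed.
#' @return List of `nReaders * nRepeats` [VOIMask-class] objects.
#' @export
simulateReaderMasks <- function(trueMask, jitter, nReaders = 2L,
                                nRepeats = 2L, seed = 1L) {
  stopifnot(is(trueMask, "VOIMask"))
  if (!any(maskArray(trueMask)) && !isTumorBed(trueMask))
    stop("truth mask is empty and not flagged tumor-bed")
  jitter <- as.numeric(jitter)
  if (length(jitter) == 1L) jitter <- c(jitter, jitter / 2)
  if (length(jitter) != 2L || any(jitter < 0) || jitter[1] < jitter[2])
    stop("jitter must be c(inter, intra) with inter >= intra >= 0")
  m <- maskArray(trueMask)
  gs <- dim(m)
  out <- vector("list", nReaders * nRepeats)
  if (all(jitter == 0)) {
    k <- 0L
    for (r in seq_len(nReaders)) for (rep in seq_len(nRepeats)) {
      k <- k + 1L
      out[[k]] <- VOIMask(m, patientId = patientId(trueMask),
                          timepoint = timepoint(trueMask),
                          readerId = sprintf("R%d", r), repeatIndex = rep - 1L,
                          tumorBed = isTumorBed(trueMask))
    }
    return(out)
  }
  if (!any(m)) {                     # empty tumor-bed truth: copy as-is
    k <- 0L
    for (r in seq_len(nReaders)) for (rep in seq_len(nRepeats)) {
      k <- k + 1L
      out[[k]] <- VOIMask(m, patientId = patientId(trueMask),
                          timepoint = timepoint(trueMask),
                          readerId = sprintf("R%d", r), repeatIndex = rep - 1L,
                          tumorBed = TRUE)
    }
    return(out)
  }
  bb <- expandBbox(maskBbox(m, gs), 5L, gs)
  ds <- lengths(bb)
  msub <- array(as.numeric(m[bb[[1]], bb[[2]], bb[[3]]]), dim = ds)
  soft <- gaussSmooth3D(msub, c(1.2, 1.2, 0.8))
  amp <- 0.25
  k <- 0L
  for (r in seq_len(nReaders)) {
    fReader <- withSeed(stableHash(seed, patientId(trueMask),
                                   timepoint(trueMask), "reader", r),
                        smoothNoiseField(ds, c(2, 2, 1)))
    for (rep in seq_len(nRepeats)) {
      fRepeat <- withSeed(stableHash(seed, patientId(trueMask),
                                     timepoint(trueMask), "repeat", r, rep),
                          smoothNoiseField(ds, c(2, 2, 1)))
      field <- soft + amp * (jitter[1] * fReader + jitter[2] * fRepeat)
      pm <- array(FALSE, dim = gs)
      pm[bb[[1]], bb[[2]], bb[[3]]] <- field > 0.5
      k <- k + 1L
      out[[k]] <- VOIMask(pm, patientId = patientId(trueMask),
                          timepoint = timepoint(trueMask),
                          readerId = sprintf("R%d", r), repeatIndex = rep - 1L,
                          tumorBed = !any(pm) || isTumorBed(trueMask))
    }
  }
  out
}

#' Dice overlap between two binary masks
#'
#' @param a,b Logical arrays or [VOIMask-class] objects of equal shape.
#' @return `2|a n b| / (|a| + |b|)`; 1 when both are empty.
#' @export
diceOverlap <- function(a, b) {
  if (is(a, "VOIMask")) a <- maskArray(a)
  if (is(b, "VOIMask")) b <- maskArray(b)
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
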