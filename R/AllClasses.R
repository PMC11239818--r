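#' @title Core S4 classes
#' @name DeltaRadiomics-classes
#' @description
#' `MRIStudy` holds one patient-timepoint's aligned volumes (DCE
#' early-subtraction, DWI b=100 and b=800, and the derived ADC map) with
#' voxel geometry. `VOIMask` is a binary 3D tumor mask tied to a study,
#' reader, and repeat index. `ModelResult` stores a fitted multivariate
#' model's selection and performance. `AgreementReport` stores per-feature
#' inter-/intrareader reproducibility statistics.
NULL

setClass("MRIStudy",
  representation(
    patientId    = "character",
    timepoint    = "character",
    dceSubtraction = "array",
    dwiB100      = "array",
    dwiB800      = "array",
    adc          = "array",
    voxelSpacing = "numeric",
    metadata     = "list"
  )
)

setValidity("MRIStudy", function(object) {
  msgs <- character()
  d <- dim(object@dceSubtraction)
  if (length(d) != 3L) msgs <- c(msgs, "volumes must be 3D arrays")
  for (s in c("dwiB100", "dwiB800", "adc")) {
    v <- slot(object, s)
    if (length(v) && !identical(dim(v), d))
      msgs <- c(msgs, sprintf("%s shape differs from dceSubtraction", s))
  }
  if (length(object@voxelSpacing) != 3L || any(object@voxelSpacing <= 0))
    msgs <- c(msgs, "voxelSpacing must be 3 positive values (mm)")
  if (!object@timepoint %in% c("BL", "C2", "C4"))
    msgs <- c(msgs, "timepoint must be one of BL, C2, C4")
  if (length(msgs)) msgs else TRUE
})

setClass("VOIMask",
  representation(
    patientId   = "character",
    timepoint   = "character",
    readerId    = "character",
    repeatIndex = "integer",
    mask        = "array",
    tumorBed    = "logical"
  ),
  prototype(readerId = "truth", repeatIndex = 0L, tumorBed = FALSE)
)

setValidity("VOIMask", function(object) {
  msgs <- character()
  if (length(dim(object@mask)) != 3L) msgs <- c(msgs, "mask must be 3D")
  if (!is.logical(object@mask)) msgs <- c(msgs, "mask must be logical")
  if (!any(object@mask) && !object@tumorBed)
    msgs <- c(msgs, "empty mask must carry the tumor-bed flag")
  if (object@repeatIndex < 0L) msgs <- c(msgs, "repeatIndex must be >= 0")
  if (length(msgs)) msgs else TRUE
})

setClass("ModelResult",
  representation(
    spec             = "list",
    selectedFeatures = "character",
    coefficients     = "numeric",
    aucTrain         = "numeric",
    aucTest          = "numeric",
    accuracyTest     = "numeric",
    aucCI            = "numeric",
    pValue           = "numeric"
  )
)

setValidity("ModelResult", function(object) {
  msgs <- character()
  if (length(object@aucCI) == 2L && length(object@aucTest) == 1L &&
      is.finite(object@aucTest) &&
      (object@aucTest < object@aucCI[1] - 1e-8 ||
       object@aucTest > object@aucCI[2] + 1e-8))
    msgs <- c(msgs, "confidence interval must contain the test AUC")
  if (length(msgs)) msgs else TRUE
})

setClass("AgreementReport",
  representation(
    perFeature = "data.frame",
    summary    = "list",
    counts     = "data.frame"
  )
)

setValidity("AgreementReport", function(object) {
  pf <- object@perFeature
  msgs <- character()
  need <- c("feature", "pearson_r", "wilcoxon_p", "variance_ratio")
  if (!all(need %in% names(pf)))
    msgs <- c(msgs, paste("perFeature must contain", paste(need, collapse = ", ")))
  r <- pf$pearson_r
  if (length(r) && any(abs(r) > 1 + 1e-8, na.rm = TRUE))
    msgs <- c(msgs, "pearson_r must lie in [-1, 1]")
  vr <- pf$variance_ratio
  if (length(vr) && any(vr < 0, na.rm = TRUE))
    msgs <- c(msgs, "variance_ratio must be >= 0")
  if (length(msgs)) msgs else TRUE
})

## ---- constructors --------------------------------------------------------

#' Construct an MRIStudy
#'
#' @param patientId Patient identifier.
#' @param timepoint One of `"BL"`, `"C2"`, `"C4"`.
#' @param dceSubtraction 3D array, 2.5-min early DCE subtraction signal.
#' @param dwiB100,dwiB800 3D arrays, DWI signal at b = 100 / 800 s/mm^2.
#'   Either may be `NULL` when absent.
#' @param adc 3D array, apparent diffusion coefficient (mm^2/s), or `NULL`.
#' @param voxelSpacing Numeric length-3, voxel edge lengths in mm.
#' @param metadata Free-form list (e.g. truth masks from the simulator).
#' @return An [MRIStudy-class] object.
#' @export
MRIStudy <- function(patientId, timepoint, dceSubtraction,
                     dwiB100 = NULL, dwiB800 = NULL, adc = NULL,
                     voxelSpacing = c(1, 1, 1), metadata = list()) {
  empty <- array(numeric(0), dim = c(0, 0, 0))
  new("MRIStudy",
      patientId = as.character(patientId), timepoint = as.character(timepoint),
      dceSubtraction = dceSubtraction,
      dwiB100 = if (is.null(dwiB100)) empty else dwiB100,
      dwiB800 = if (is.null(dwiB800)) empty else dwiB800,
      adc = if (is.null(adc)) empty else adc,
      voxelSpacing = as.numeric(voxelSpacing), metadata = metadata)
}

#' Construct a VOIMask
#'
#' @param mask Logical (or coercible) 3D array.
#' @param patientId,timepoint,readerId,repeatIndex Identity of the contour.
#' @param tumorBed Flag set when the contour marks a tumor bed (tumor no
#'   longer visible); an empty mask is only legal with this flag.
#' @return A [VOIMask-class] object.
#' @export
VOIMask <- function(mask, patientId = "unknown", timepoint = "BL",
                    readerId = "truth", repeatIndex = 0L, tumorBed = FALSE) {
  storage.mode(mask) <- "logical"
  new("VOIMask", patientId = as.character(patientId),
      timepoint = as.character(timepoint), readerId = as.character(readerId),
      repeatIndex = as.integer(repeatIndex), mask = mask,
      tumorBed = isTRUE(tumorBed))
}

## ---- accessors -----------------------------------------------------------

#' Accessors for MRIStudy and VOIMask
#'
#' @param object An [MRIStudy-class] or [VOIMask-class].
#' @return `voxelSpacing()` the mm spacing; `maskArray()` the logical 3D
#'   array; `studyVolume()` the named volume; `isTumorBed()` the tumor-bed
#'   flag; `patientId()`/`timepoint()` identifiers.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "MRIStudy", function(object) object@voxelSpacing)

#' @rdname accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setMethod("maskArray", "VOIMask", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("isTumorBed", function(object) standardGeneric("isTumorBed"))
#' @rdname accessors
#' @export
setMethod("isTumorBed", "VOIMask", function(object) object@tumorBed)

#' @rdname accessors
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setMethod("patientId", "MRIStudy", function(object) object@patientId)
#' @rdname accessors
#' @export
setMethod("patientId", "VOIMask", function(object) object@patientId)

#' @rdname accessors
#' @export
setGeneric("timepoint", function(object) standardGeneric("timepoint"))
#' @rdname accessors
#' @export
setMethod("timepoint", "MRIStudy", function(object) object@timepoint)
#' @rdname accessors
#' @export
setMethod("timepoint", "VOIMask", function(object) object@timepoint)

#' @rdname accessors
#' @param name Volume name: `"dce"`, `"dwi_b100"`, `"dwi_b800"`, or `"adc"`.
#' @export
setGeneric("studyVolume", function(object, name) standardGeneric("studyVolume"))
#' @rdname accessors
#' @export
setMethod("studyVolume", "MRIStudy", function(object, name) {
  v <- switch(match.arg(name, c("dce", "dwi_b100", "dwi_b800", "adc")),
              dce = object@dceSubtraction, dwi_b100 = object@dwiB100,
              dwi_b800 = object@dwiB800, adc = object@adc)
  if (!length(v)) NULL else v
})

## ---- show ----------------------------------------------------------------

setMethod("show", "MRIStudy", function(object) {
  d <- dim(object@dceSubtraction)
  cat(sprintf("MRIStudy %s @ %s  [%s voxels, %s mm]\n",
              object@patientId, object@timepoint,
              paste(d, collapse = "x"),
              paste(signif(object@voxelSpacing, 3), collapse = "x")))
  have <- c("dce",
            if (length(object@dwiB100)) "dwi_b100",
            if (length(object@dwiB800)) "dwi_b800",
            if (length(object@adc)) "adc")
  cat("  volumes:", paste(have, collapse = ", "), "\n")
})

setMethod("show", "VOIMask", function(object) {
  cat(sprintf("VOIMask %s @ %s reader=%s repeat=%d  (%d voxels%s)\n",
              object@patientId, object@timepoint, object@readerId,
              object@repeatIndex, sum(object@mask),
              if (object@tumorBed) ", tumor bed" else ""))
})

setMethod("show", "ModelResult", function(object) {
  cat(sprintf("ModelResult [%s]\n", paste(unlist(object@spec$family),
                                          collapse = " + ")))
  cat(sprintf("  %d selected features; AUC train %.3f / test %.3f (CI %.3f-%.3f), acc %.3f, p %.3g\n",
              length(object@selectedFeatures), object@aucTrain, object@aucTest,
              object@aucCI[1], object@aucCI[2], object@accuracyTest,
              object@pValue))
})

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport over %d features\n", nrow(object@perFeature)))
  s <- object@summary
  cat(sprintf("  variance ratio: mean %.4f, median %.4f, range %.4f-%.4f, sd %.4f\n",
              s$mean, s$median, s$range[1], s$range[2], s$sd))
})
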