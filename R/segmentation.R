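#' Segmentation parameters
#'
#' @param thresholdMethod `"otsu"` (default; parameter-free histogram
#'   threshold maximizing between-class variance over the rough-contour
#'   intensities) or `"fixed_quantile"`.
#' @param quantile Quantile in (0, 1), used by `"fixed_quantile"`.
#' @param minComponentVoxels Connected components (26-connectivity) smaller
#'   than this are removed as speckle.
#' @return A list of class `SegmentationParams`.
#' @export
segmentationParams <- function(thresholdMethod = c("otsu", "fixed_quantile"),
                               quantile = 0.5, minComponentVoxels = 5L) {
  thresholdMethod <- match.arg(thresholdMethod)
  if (quantile <= 0 || quantile >= 1) stop("quantile must lie in (0, 1)")
  structure(list(thresholdMethod = thresholdMethod, quantile = quantile,
                 minComponentVoxels = as.integer(minComponentVoxels)),
            class = "SegmentationParams")
}

## Otsu threshold over the exact empirical distribution: every cut between
## consecutive distinct values is scored by between-class variance. Returns
## a threshold t such that the upper class is {x >= t}. Constant input
## returns -Inf (degenerate: everything is upper class).
otsuThreshold <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2L) return(-Inf)
  tab <- table(factor(x, levels = u))
  n <- length(x)
  w <- cumsum(as.numeric(tab)) / n           # weight of lower class per cut
  csum <- cumsum(as.numeric(tab) * u)
  mu <- csum[length(u)] / n
  muLow <- csum / (w * n)
  between <- w * (1 - w) * (muLow - (mu - w * muLow) / (1 - w))^2
  between <- between[-length(u)]             # cut after u[k], k < |u|
  k <- which.max(between)
  (u[k] + u[k + 1]) / 2
}

#' Refine a rough contour by histogram thresholding
#'
#' Mirrors semi-automatic VOI refinement: a hand-drawn envelope is reduced
#' to the voxels whose intensity reaches a threshold computed from the
#' histogram of intensities inside the envelope, then small speckle
#' components are pruned. If every voxel falls below threshold the result
#' is an empty VOI flagged as tumor bed. A constant-intensity region is
#' returned unchanged (the threshold is degenerate).
#'
#' @param volume 3D scalar array aligned with the contour.
#' @param rough A [VOIMask-class] (the hand-drawn envelope), nonempty.
#' @param params A [segmentationParams()].
#' @param threshold Optional fixed intensity threshold; when supplied the
#'   histogram rule is skipped (this makes the operation idempotent: the
#'   computed threshold is attached to the result as attribute
#'   `"threshold"` and can be fed back in).
#' @return A [VOIMask-class], always a subset of the rough mask, with the
#'   applied threshold in `attr(, "threshold")`.
#' @export
thresholdSegment <- function(volume, rough, params = segmentationParams(),
                             threshold = NULL) {
  stopifnot(is(rough, "VOIMask"))
  rm <- maskArray(rough)
  if (!identical(dim(volume), dim(rm)))
    stop("volume and rough mask shapes differ")
  if (!any(rm)) {
    if (isTumorBed(rough)) return(rough)
    stop("rough mask is empty")
  }
  vals <- volume[rm]
  thr <- if (!is.null(threshold)) threshold else
    switch(params$thresholdMethod,
           otsu = otsuThreshold(vals),
           fixed_quantile = quantile(vals, params$quantile, names = FALSE))
  out <- rm & volume >= thr
  out <- pruneSmallComponents(out, params$minComponentVoxels)
  res <- VOIMask(out, patientId = patientId(rough),
                 timepoint = timepoint(rough), readerId = rough@readerId,
                 repeatIndex = rough@repeatIndex, tumorBed = !any(out))
  attr(res, "threshold") <- thr
  res
}

#' Remove excluded regions (necrosis, clip artifacts) from a VOI
#'
#' @param voi A [VOIMask-class].
#' @param exclusion Logical 3D array (or [VOIMask-class]) of voxels to drop.
#' @return `voi AND NOT exclusion`; if nothing survives, the empty VOI is
#'   flagged tumor bed so downstream features are still computed over the
#'   contoured bed.
#' @export
excludeRegions <- function(voi, exclusion) {
  stopifnot(is(voi, "VOIMask"))
  if (is(exclusion, "VOIMask")) exclusion <- maskArray(exclusion)
  m <- maskArray(voi)
  if (!identical(dim(m), dim(exclusion))) stop("shape mismatch")
  out <- m & !exclusion
  VOIMask(out, patientId = patientId(voi), timepoint = timepoint(voi),
          readerId = voi@readerId, repeatIndex = voi@repeatIndex,
          tumorBed = isTumorBed(voi) || !any(out))
}

#' Select the index lesion among candidates
#'
#' The largest lesion (voxel count times voxel volume) is taken as the
#' index carcinoma; exact volume ties are broken by the lexicographically
#' smallest centroid.
#'
#' @param masks Nonempty list of [VOIMask-class] candidates on the DCE
#'   volume.
#' @param voxelSpacing mm per axis (for the volume; ties are unaffected).
#' @return The selected [VOIMask-class].
#' @export
selectIndexLesion <- function(masks, voxelSpacing = c(1, 1, 1)) {
  if (!length(masks)) stop("no candidate lesions")
  vol <- vapply(masks, function(m) sum(maskArray(m)) * prod(voxelSpacing),
                numeric(1))
  best <- which(vol == max(vol))
  if (length(best) > 1L) {
    cent <- t(vapply(masks[best], function(m) {
      colMeans(arrayInd(which(maskArray(m)), dim(maskArray(m))))
    }, numeric(3)))
    ord <- do.call(order, as.data.frame(cent))
    best <- best[ord[1]]
  }
  masks[[best]]
}
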