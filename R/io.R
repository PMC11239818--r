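studyFileNames <- c(dce = "dce_sub.nii.gz", dwi_b100 = "dwi_b100.nii.gz",
                    dwi_b800 = "dwi_b800.nii.gz", adc = "adc.nii.gz")

#' Write / read an MRIStudy as NIfTI-1
#'
#' Volumes are stored as `dce_sub.nii.gz`, `dwi_b100.nii.gz`,
#' `dwi_b800.nii.gz` and `adc.nii.gz` under
#' `<dir>/<patient_id>/<timepoint>/`, with the voxel spacing in the NIfTI
#' header. Reading tolerates a missing `dwi_b100`/`adc` pair (the study
#' loads with those volumes absent) but fails, naming the file, when
#' shapes disagree.
#'
#' @param study An [MRIStudy-class].
#' @param dir Cohort root directory.
#' @return `writeStudy` the study directory (invisibly); `readStudy` an
#'   [MRIStudy-class].
#' @export
writeStudy <- function(study, dir) {
  sdir <- file.path(dir, patientId(study), timepoint(study))
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(studyFileNames)) {
    v <- studyVolume(study, nm)
    if (is.null(v)) next
    v[!is.finite(v)] <- 0          # NIfTI stores a dense grid; mask later
    img <- RNifti::asNifti(v)
    RNifti::pixdim(img) <- voxelSpacing(study)
    RNifti::writeNifti(img, file.path(sdir, studyFileNames[[nm]]))
  }
  invisible(sdir)
}

#' @rdname writeStudy
#' @param pid,tp Patient id and timepoint of the study to load.
#' @export
readStudy <- function(dir, pid, tp) {
  sdir <- file.path(dir, pid, tp)
  paths <- file.path(sdir, studyFileNames)
  names(paths) <- names(studyFileNames)
  if (!file.exists(paths[["dce"]]))
    stop("missing DCE volume: ", paths[["dce"]])
  vols <- list(); spacing <- NULL; refDim <- NULL
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) { vols[[nm]] <- NULL; next }
    img <- RNifti::readNifti(paths[[nm]])
    a <- array(as.numeric(img), dim = dim(img))
    if (is.null(refDim)) {
      refDim <- dim(a)
      spacing <- RNifti::pixdim(img)[1:3]
    } else if (!identical(dim(a), refDim)) {
      stop("volume shape mismatch in ", paths[[nm]])
    }
    vols[[nm]] <- a
  }
  MRIStudy(pid, tp, dceSubtraction = vols$dce, dwiB100 = vols$dwi_b100,
           dwiB800 = vols$dwi_b800, adc = vols$adc, voxelSpacing = spacing,
           metadata = list(adcAbsent = is.null(vols$adc)))
}

#' Write / read a VOI mask as NIfTI-1
#'
#' Masks live next to the study volumes as
#' `mask_r<reader>_k<repeat>.nii.gz`.
#'
#' @param mask A [VOIMask-class].
#' @param dir Cohort root directory.
#' @export
writeMask <- function(mask, dir) {
  sdir <- file.path(dir, patientId(mask), timepoint(mask))
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  fn <- sprintf("mask_r%s_k%d.nii.gz", mask@readerId, mask@repeatIndex)
  img <- RNifti::asNifti(array(as.integer(maskArray(mask)),
                               dim = dim(maskArray(mask))))
  RNifti::writeNifti(img, file.path(sdir, fn))
  invisible(file.path(sdir, fn))
}

#' @rdname writeMask
#' @param pid,tp,readerId,repeatIndex Identity of the mask to load.
#' @param tumorBed Tumor-bed flag to attach (not stored in NIfTI).
#' @export
readMask <- function(dir, pid, tp, readerId = "truth", repeatIndex = 0L,
                     tumorBed = FALSE) {
  fn <- file.path(dir, pid, tp,
                  sprintf("mask_r%s_k%d.nii.gz", readerId, repeatIndex))
  if (!file.exists(fn)) stop("missing mask: ", fn)
  img <- RNifti::readNifti(fn)
  VOIMask(array(as.numeric(img) > 0.5, dim = dim(img)), patientId = pid,
          timepoint = tp, readerId = readerId, repeatIndex = repeatIndex,
          tumorBed = tumorBed)
}

#' Cohort characteristics comparison (Table-1 style)
#'
#' Compares clinical covariates between outcome groups: continuous
#' variables by the two-sided Wilcoxon rank-sum test, categorical
#' variables by Fisher's exact test (falling back to a seed-controlled
#' Monte-Carlo p-value for large tables). Categorical rows report counts
#' and percentages per group; continuous rows report median (range).
#'
#' @param clinical `data.frame` with `patient_id` and covariates.
#' @param labels Binary outcome vector (defaults to `clinical$pcr`).
#' @param mcSeed Seed for Monte-Carlo Fisher p-values.
#' @return `data.frame` with columns `variable`, `level`, `n_total`,
#'   `pct_total`, `n_neg`, `pct_neg`, `n_pos`, `pct_pos`,
#'   `summary_total`, `summary_neg`, `summary_pos`, `p_value` (repeated
#'   within a variable).
#' @export
cohortStats <- function(clinical, labels = clinical$pcr, mcSeed = 1L) {
  labels <- as.integer(labels)
  if (min(table(labels)) < 2) stop("need >= 2 patients per group")
  vars <- setdiff(names(clinical), c("patient_id", "pcr"))
  rows <- list()
  for (v in vars) {
    x <- clinical[[v]]
    if (is.numeric(x)) {
      p <- suppressWarnings(
        wilcox.test(x[labels == 1], x[labels == 0], exact = FALSE)$p.value)
      fmt <- function(z) sprintf("%g (%g-%g)", median(z), min(z), max(z))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = "median (range)",
        n_total = NA_integer_, pct_total = NA_real_,
        n_neg = NA_integer_, pct_neg = NA_real_,
        n_pos = NA_integer_, pct_pos = NA_real_,
        summary_total = fmt(x), summary_neg = fmt(x[labels == 0]),
        summary_pos = fmt(x[labels == 1]), p_value = p,
        stringsAsFactors = FALSE)
    } else {
      x <- as.character(x)
      present <- table(x) > 0
      lv <- names(present)[present]
      tab <- table(factor(x, levels = lv), labels)
      p <- if (nrow(tab) < 2) NA_real_ else     # single observed level
        tryCatch(fisher.test(tab)$p.value,
                 error = function(e) withSeed(stableHash(mcSeed, v),
                   fisher.test(tab, simulate.p.value = TRUE,
                               B = 1e5)$p.value))
      for (l in lv) {
        nT <- sum(x == l)
        n0 <- sum(x == l & labels == 0)
        n1 <- sum(x == l & labels == 1)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = l,
          n_total = nT, pct_total = round(100 * nT / length(x)),
          n_neg = n0, pct_neg = round(100 * n0 / sum(labels == 0)),
          n_pos = n1, pct_pos = round(100 * n1 / sum(labels == 1)),
          summary_total = sprintf("%d (%d%%)", nT,
                                  round(100 * nT / length(x))),
          summary_neg = sprintf("%d (%d%%)", n0,
                                round(100 * n0 / sum(labels == 0))),
          summary_pos = sprintf("%d (%d%%)", n1,
                                round(100 * n1 / sum(labels == 1))),
          p_value = p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
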