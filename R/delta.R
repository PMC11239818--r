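#' Delta radiomics: between-timepoint feature differences
#'
#' `absoluteDifference()` returns `late - early` per feature;
#' `relativeDifference()` returns `(late - early) / |early|`, with a guard:
#' features whose early value is within `epsilon` of zero become `NA`
#' rather than infinite. A missing value in either timepoint propagates to
#' a missing delta for that feature only (feature-wise, never patient-wise).
#' The three ordered timepoint pairs are C2/BL, C4/BL, C4/C2 and "X/Y" is
#' read as "change between X and Y".
#'
#' @param fvLate,fvEarly Named feature vectors with identical schemas (the
#'   names must match exactly, in order).
#' @param epsilon Guard below which an early value counts as zero.
#' @return Named feature vector of the same schema.
#' @export
absoluteDifference <- function(fvLate, fvEarly) {
  checkSchema(fvLate, fvEarly)
  out <- as.numeric(fvLate) - as.numeric(fvEarly)
  names(out) <- names(fvLate)
  out
}

#' @rdname absoluteDifference
#' @export
relativeDifference <- function(fvLate, fvEarly, epsilon = 1e-12) {
  checkSchema(fvLate, fvEarly)
  early <- as.numeric(fvEarly)
  out <- (as.numeric(fvLate) - early) / abs(early)
  out[!is.na(early) & abs(early) <= epsilon] <- NA_real_
  names(out) <- names(fvLate)
  out
}

checkSchema <- function(a, b) {
  if (is.null(names(a)) || !identical(names(a), names(b)))
    stop("feature schemas differ between the two vectors")
  invisible(TRUE)
}

.deltaPairs <- list(c("C2", "BL"), c("C4", "BL"), c("C4", "C2"))

#' Assemble the per-patient feature table across timepoints and deltas
#'
#' Stacks raw timepoint features and the absolute/relative differences over
#' all available ordered timepoint pairs into one features-by-patients
#' `SummarizedExperiment`. With all three timepoints and both sequences the
#' table has 310 x 18 rows: 3 raw timepoints + 3 pairs x 2 delta modes,
#' each for DCE and DWI. Row metadata records `sequence`, `block` (e.g.
#' `"BL"`, `"AD_C2_BL"`, `"RD_C4_C2"`) and base `feature` name; column data
#' holds the clinical table with the pCR label.
#'
#' @param features Nested list: `features[[patient_id]][[sequence]][[timepoint]]`
#'   is a named feature vector.
#' @param clinical Clinical `data.frame` from [generateCohort()] (must
#'   contain `patient_id` and `pcr`).
#' @param epsilon Relative-difference guard; see [relativeDifference()].
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"features"`.
#' @export
assembleFeatureTable <- function(features, clinical, epsilon = 1e-12) {
  stopifnot(all(c("patient_id", "pcr") %in% names(clinical)))
  pids <- clinical$patient_id
  stopifnot(all(pids %in% names(features)))
  sequences <- names(features[[pids[1]]])
  tps <- names(features[[pids[1]]][[sequences[1]]])
  pairs <- Filter(function(p) all(p %in% tps), .deltaPairs)

  blockRows <- function(pid) {
    unlist(lapply(sequences, function(sq) {
      raw <- features[[pid]][[sq]]
      blocks <- c(
        setNames(raw, tps),
        setNames(lapply(pairs, function(p)
          absoluteDifference(raw[[p[1]]], raw[[p[2]]])),
          vapply(pairs, function(p) paste("AD", p[1], p[2], sep = "_"), "")),
        setNames(lapply(pairs, function(p)
          relativeDifference(raw[[p[1]]], raw[[p[2]]], epsilon)),
          vapply(pairs, function(p) paste("RD", p[1], p[2], sep = "_"), "")))
      unlist(blocks, use.names = FALSE)
    }), use.names = FALSE)
  }
  mat <- vapply(pids, blockRows, numeric(
    length(sequences) * (length(tps) + 2 * length(pairs)) *
      length(features[[pids[1]]][[sequences[1]]][[1]])))
  baseNames <- names(features[[pids[1]]][[sequences[1]]][[1]])
  blockNames <- c(tps,
                  vapply(pairs, function(p) paste("AD", p[1], p[2], sep = "_"), ""),
                  vapply(pairs, function(p) paste("RD", p[1], p[2], sep = "_"), ""))
  rd <- do.call(rbind, lapply(sequences, function(sq)
    do.call(rbind, lapply(blockNames, function(b)
      data.frame(sequence = sq, block = b, feature = baseNames,
                 stringsAsFactors = FALSE)))))
  rownames(mat) <- paste(rd$sequence, rd$block, rd$feature, sep = ".")
  colnames(mat) <- pids
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat),
    rowData = S4Vectors::DataFrame(rd),
    colData = S4Vectors::DataFrame(clinical, row.names = pids))
}

#' Select feature rows belonging to one or more blocks
#'
#' @param se Feature table from [assembleFeatureTable()].
#' @param blocks Character block labels (e.g. `c("RD_C2_BL")`).
#' @param sequences Sequences to keep (default both).
#' @return Subset `SummarizedExperiment`.
#' @export
selectBlocks <- function(se, blocks, sequences = c("DCE", "DWI")) {
  rd <- SummarizedExperiment::rowData(se)
  keep <- rd$block %in% blocks & rd$sequence %in% sequences
  if (!any(keep)) stop("no features match the requested blocks")
  se[keep, ]
}
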