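#' Pipeline configuration
#'
#' Collects the parameter blocks for a full synthetic-cohort run. Unknown
#' keys in any block are rejected.
#'
#' @param cohort A [cohortConfig()].
#' @param segmentation A [segmentationParams()].
#' @param quantization A [quantizationParams()].
#' @param glcm A [glcmConfig()].
#' @param epsilon Relative-difference guard.
#' @param screening List with `aucFloor`, `pCeiling`.
#' @param modeling List with `trainFraction`, `extraCombos`, `families`
#'   (blocks to fit; `NULL` fits the whole grid), `cv3` (logical: also run
#'   3-fold CV for each fitted model), and optional `alphaGrid`.
#' @param agreement List with `jitter` (`c(inter, intra)`), `nReaders`,
#'   `nRepeats`, `nPatients` (subset size), `timepoint`, and `sequence`.
#' @param outputDir Directory for outputs, or `NULL` to skip writing.
#' @param seed Global pipeline seed.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(cohort = cohortConfig(),
                           segmentation = segmentationParams(),
                           quantization = quantizationParams(),
                           glcm = glcmConfig(),
                           epsilon = 1e-12,
                           screening = list(aucFloor = 0.7, pCeiling = 0.001),
                           modeling = list(trainFraction = 2 / 3,
                                           extraCombos = list(c("C4", "AD_C4_BL")),
                                           families = NULL, cv3 = FALSE,
                                           alphaGrid = seq(0.1, 1, 0.1)),
                           agreement = list(jitter = c(0.3, 0.15),
                                            nReaders = 2L, nRepeats = 2L,
                                            nPatients = 20L,
                                            timepoint = "BL",
                                            sequence = "DCE"),
                           outputDir = NULL, seed = 1L) {
  checkKeys <- function(block, allowed, nm) {
    bad <- setdiff(names(block), allowed)
    if (length(bad))
      stop("unknown ", nm, " keys: ", paste(bad, collapse = ", "))
  }
  checkKeys(screening, c("aucFloor", "pCeiling"), "screening")
  checkKeys(modeling, c("trainFraction", "extraCombos", "families", "cv3",
                        "alphaGrid"), "modeling")
  checkKeys(agreement, c("jitter", "nReaders", "nRepeats", "nPatients",
                         "timepoint", "sequence"), "agreement")
  stopifnot(inherits(cohort, "CohortConfig"),
            inherits(segmentation, "SegmentationParams"),
            inherits(quantization, "QuantizationParams"),
            inherits(glcm, "GLCMConfig"))
  structure(list(cohort = cohort, segmentation = segmentation,
                 quantization = quantization, glcm = glcm,
                 epsilon = epsilon, screening = screening,
                 modeling = modeling, agreement = agreement,
                 outputDir = outputDir, seed = as.integer(seed)),
            class = "PipelineConfig")
}

## Rough manual envelope around a truth mask: softened and rethresholded
## low, emulating a generous hand contour.
roughEnvelope <- function(truth) {
  m <- maskArray(truth)
  d <- dim(m)
  bb <- expandBbox(maskBbox(m, d), 5L, d)
  msub <- array(as.numeric(m[bb[[1]], bb[[2]], bb[[3]]]), dim = lengths(bb))
  soft <- array(0, dim = d)
  soft[bb[[1]], bb[[2]], bb[[3]]] <- gaussSmooth3D(msub, c(1.5, 1.5, 1))
  VOIMask(soft > 0.05 | m, patientId = patientId(truth),
          timepoint = timepoint(truth), readerId = truth@readerId,
          tumorBed = isTumorBed(truth))
}

## Segment one simulated study and return its refined analysis VOI.
segmentStudy <- function(study, segParams) {
  truth <- study@metadata$truthMask
  rough <- roughEnvelope(truth)
  voi <- thresholdSegment(studyVolume(study, "dce"), rough, segParams)
  nec <- study@metadata$necrosisMask
  if (any(nec)) voi <- excludeRegions(voi, nec)
  voi
}

#' Simulate, segment and extract features for a whole cohort
#'
#' Runs the image-level half of the pipeline: per patient and timepoint,
#' simulate the study, refine the rough envelope by histogram
#' thresholding, remove the necrotic core, and extract DCE and DWI
#' feature vectors; then assemble the timepoint + delta feature table.
#'
#' @param config A [cohortConfig()].
#' @param segmentation,quantization,glcm Parameter objects.
#' @param epsilon Relative-difference guard.
#' @param clinical Optional pre-generated cohort table.
#' @return List: `se` (the `SummarizedExperiment` feature table),
#'   `clinical`.
#' @export
extractCohortFeatures <- function(config,
                                  segmentation = segmentationParams(),
                                  quantization = quantizationParams(),
                                  glcm = glcmConfig(),
                                  epsilon = 1e-12,
                                  clinical = NULL) {
  if (is.null(clinical)) clinical <- generateCohort(config)
  features <- lapply(seq_len(nrow(clinical)), function(i) {
    rec <- clinical[i, ]
    perTp <- lapply(config$timepoints, function(tp) {
      study <- simulateStudy(rec, tp, config)
      voi <- segmentStudy(study, segmentation)
      list(DCE = extractFeatureVector(study, voi, "DCE", quantization, glcm),
           DWI = extractFeatureVector(study, voi, "DWI", quantization, glcm))
    })
    names(perTp) <- config$timepoints
    list(DCE = lapply(perTp, `[[`, "DCE"), DWI = lapply(perTp, `[[`, "DWI"))
  })
  names(features) <- clinical$patient_id
  list(se = assembleFeatureTable(features, clinical, epsilon),
       clinical = clinical)
}

#' Reader-agreement measurements for a cohort subset
#'
#' Simulates reader contours (with repeats) on the chosen timepoint,
#' extracts features per contour, and returns the long-format table
#' consumed by [agreementReport()].
#'
#' @param config A [cohortConfig()].
#' @param clinical Cohort table (first `nPatients` rows are used).
#' @param jitter `c(inter, intra)` contour jitter.
#' @param nReaders,nRepeats Reader/repeat counts.
#' @param nPatients Number of patients to contour.
#' @param tp Timepoint to contour.
#' @param sequence Sequence to extract (default DCE, mirroring the
#'   agreement analysis).
#' @param quantization,glcm Parameter objects.
#' @param seed Integer seed for the contour simulation.
#' @return Long-format `data.frame` (`patient_id`, `reader_id`,
#'   `repeat_index`, then one column per feature).
#' @export
readerMeasurements <- function(config, clinical, jitter = c(0.3, 0.15),
                               nReaders = 2L, nRepeats = 2L, nPatients = 20L,
                               tp = "BL", sequence = "DCE",
                               quantization = quantizationParams(),
                               glcm = glcmConfig(), seed = 1L) {
  sub <- head(clinical, nPatients)
  rows <- list()
  for (i in seq_len(nrow(sub))) {
    rec <- sub[i, ]
    study <- simulateStudy(rec, tp, config)
    truth <- study@metadata$truthMask
    masks <- simulateReaderMasks(truth, jitter, nReaders, nRepeats,
                                 seed = stableHash(seed, rec$patient_id))
    for (mk in masks) {
      fv <- extractFeatureVector(study, mk, sequence, quantization, glcm)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(patient_id = rec$patient_id, reader_id = mk@readerId,
                   repeat_index = mk@repeatIndex, stringsAsFactors = FALSE),
        as.data.frame(as.list(fv), optional = TRUE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Stages, in order: cohort generation; simulation + segmentation +
#' feature extraction; delta feature table; stratified split; univariate
#' AUC screening; multivariate model grid (elastic net, with optional
#' 3-fold CV comparison); reader-agreement analysis; clinical Table-1
#' comparison; run manifest. All randomness derives from `config$seed`;
#' re-running the same config reproduces every numeric output. When
#' `outputDir` is set, each stage writes CSV/JSON outputs and the manifest
#' records their checksums.
#'
#' @param config A [pipelineConfig()].
#' @return (Invisibly) a list with `clinical`, `se`, `split`, `screening`,
#'   `models` (list of [ModelResult-class]), `modelTable`, `cv3`,
#'   `agreement`, `table1`, `manifest`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- Sys.time()
  stageLog <- character(0)
  out <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           "; completed stages: ", paste(stageLog, collapse = ", "),
           call. = FALSE))
    stageLog <<- c(stageLog, name)
    message(sprintf("[%s] done", name))
    res
  }

  ext <- stage("extract", extractCohortFeatures(
    config$cohort, config$segmentation, config$quantization, config$glcm,
    config$epsilon))
  out$clinical <- ext$clinical
  out$se <- ext$se
  nmiss <- sum(is.na(SummarizedExperiment::assay(out$se)))
  message(sprintf("  features: %d x %d patients, %d missing values",
                  nrow(out$se), ncol(out$se), nmiss))

  labels <- out$clinical$pcr
  out$split <- stage("split", stratifiedSplit(
    labels, config$modeling$trainFraction %||% (2 / 3), seed = config$seed))

  x <- SummarizedExperiment::assay(out$se, "features")
  out$screening <- stage("screen", screenFeatures(
    x[, out$split$train, drop = FALSE], x[, out$split$test, drop = FALSE],
    labels[out$split$train], labels[out$split$test],
    aucFloor = config$screening$aucFloor %||% 0.7,
    pCeiling = config$screening$pCeiling %||% 0.001))

  blocks <- unique(SummarizedExperiment::rowData(out$se)$block)
  grid <- enumerateModelGrid(
    blocks = blocks,
    extraCombos = Filter(function(cc) all(cc %in% blocks),
                         config$modeling$extraCombos %||% list()))
  fams <- config$modeling$families
  if (!is.null(fams))
    grid <- Filter(function(g) paste(g$family, collapse = "+") %in%
                     vapply(fams, paste, "", collapse = "+"), grid)
  out$grid <- grid
  enetArgs <- list()
  if (!is.null(config$modeling$alphaGrid))
    enetArgs$alphaGrid <- config$modeling$alphaGrid
  out$models <- stage("fit", lapply(grid, function(g)
    do.call(fitModelSpec, c(list(out$se, out$split, g, seed = config$seed),
                            enetArgs))))
  out$modelTable <- data.frame(
    family = vapply(grid, function(g) paste(g$family, collapse = "+"), ""),
    n_selected = vapply(out$models, function(m)
      length(m@selectedFeatures), 0L),
    auc_train = vapply(out$models, function(m) m@aucTrain, 0),
    auc_test = vapply(out$models, function(m) m@aucTest, 0),
    accuracy_test = vapply(out$models, function(m) m@accuracyTest, 0),
    auc_ci_low = vapply(out$models, function(m) m@aucCI[1], 0),
    auc_ci_high = vapply(out$models, function(m) m@aucCI[2], 0),
    p_value = vapply(out$models, function(m) m@pValue, 0),
    stringsAsFactors = FALSE)

  if (isTRUE(config$modeling$cv3)) {
    out$cv3 <- stage("cv", vapply(grid, function(g) {
      sub <- selectBlocks(out$se, g$family, g$sequences)
      d <- designMatrix(sub)
      cln <- dropDegenerate(d$x, warn = FALSE)
      do.call(crossValidate,
              c(list(cln$train, d$y, folds = 3L, learner = "elastic_net",
                     seed = config$seed), enetArgs))$auc
    }, numeric(1)))
  }

  agr <- config$agreement
  meas <- stage("agree-measure", readerMeasurements(
    config$cohort, out$clinical, jitter = agr$jitter %||% c(0.3, 0.15),
    nReaders = agr$nReaders %||% 2L, nRepeats = agr$nRepeats %||% 2L,
    nPatients = agr$nPatients %||% 20L, tp = agr$timepoint %||% "BL",
    sequence = agr$sequence %||% "DCE",
    quantization = config$quantization, glcm = config$glcm,
    seed = config$seed))
  out$agreement <- stage("agree", agreementReport(meas))

  out$table1 <- stage("table1", cohortStats(out$clinical, labels,
                                            mcSeed = config$seed))

  if (!is.null(config$outputDir)) {
    od <- config$outputDir
    dir.create(od, recursive = TRUE, showWarnings = FALSE)
    writeCsv <- function(df, fn) {
      write.csv(df, file.path(od, fn), row.names = FALSE)
      fn
    }
    files <- c(
      writeCsv(cbind(feature = rownames(x), as.data.frame(x)),
               "features.csv"),
      writeCsv(out$clinical, "clinical.csv"),
      writeCsv(out$screening, "screening.csv"),
      writeCsv(out$modelTable, "models.csv"),
      writeCsv(out$agreement@perFeature, "agreement.csv"),
      writeCsv(out$table1, "table1.csv"))
    jsonlite::write_json(out$agreement@summary,
                         file.path(od, "agreement_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(grid, file.path(od, "model_grid.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, "agreement_summary.json", "model_grid.json")
    manifest <- list(
      package_version = as.character(packageVersion("DeltaRadiomics")),
      seed = config$seed,
      config_hash = stableHash(paste(deparse(config), collapse = "")),
      stages = stageLog,
      started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      checksums = as.list(tools::md5sum(file.path(od, files))))
    names(manifest$checksums) <- files
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    out$manifest <- manifest
  }
  invisible(out)
}
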