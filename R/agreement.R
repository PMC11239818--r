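#' Per-feature Pearson correlation between two readers
#'
#' @param tableReader1,tableReader2 Patients-by-features matrices (same
#'   patients, same feature schema).
#' @return Named numeric vector of pairwise-complete Pearson r per feature;
#'   `NA` where either reader's column has zero variance.
#' @export
pearsonPerFeature <- function(tableReader1, tableReader2) {
  stopifnot(identical(dim(tableReader1), dim(tableReader2)),
            identical(colnames(tableReader1), colnames(tableReader2)))
  out <- vapply(seq_len(ncol(tableReader1)), function(j) {
    a <- tableReader1[, j]; b <- tableReader2[, j]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3 || var(a[ok]) == 0 || var(b[ok]) == 0) return(NA_real_)
    cor(a[ok], b[ok])
  }, numeric(1))
  setNames(out, colnames(tableReader1))
}

#' Per-feature Wilcoxon signed-rank test between two readers
#'
#' Two-sided paired test; zero differences are dropped (the Wilcoxon
#' convention), and a feature with all differences zero returns p = 1.
#' Exact p-values are used where `wilcox.test` provides them (small n, no
#' ties).
#'
#' @inheritParams pearsonPerFeature
#' @return Named numeric vector of p-values.
#' @export
wilcoxonPerFeature <- function(tableReader1, tableReader2) {
  stopifnot(identical(dim(tableReader1), dim(tableReader2)),
            identical(colnames(tableReader1), colnames(tableReader2)))
  out <- vapply(seq_len(ncol(tableReader1)), function(j) {
    a <- tableReader1[, j]; b <- tableReader2[, j]
    ok <- is.finite(a) & is.finite(b)
    d <- a[ok] - b[ok]
    if (!length(d) || all(d == 0)) return(1)
    suppressWarnings(wilcox.test(a[ok], b[ok], paired = TRUE)$p.value)
  }, numeric(1))
  setNames(out, colnames(tableReader1))
}

#' Inter-reader to intrareader variance ratio per feature
#'
#' For each patient and feature, the intrareader variance is the mean over
#' readers of the within-reader repeat variance, and the inter-reader
#' variance is the method-of-moments between-reader component: the variance
#' of reader means minus (intra variance / number of repeats), floored at
#' zero. The per-feature ratio is the mean inter component over patients
#' divided by the mean intra component. Features where both components are
#' zero get ratio 0; features with zero intra but positive inter variance
#' are flagged infinite and excluded from summaries with a warning.
#'
#' @param measurements Long-format `data.frame` with columns `patient_id`,
#'   `reader_id`, `repeat_index` and one numeric column per feature; every
#'   reader needs >= 2 repeats per patient.
#' @return List: `ratios` (named per-feature vector, rounded to 4
#'   decimals in the `report` element), `summary` (mean, median, range, sd
#'   over finite ratios), `excluded` (features flagged infinite).
#' @export
varianceRatio <- function(measurements) {
  keyCols <- c("patient_id", "reader_id", "repeat_index")
  stopifnot(all(keyCols %in% names(measurements)))
  featCols <- setdiff(names(measurements), keyCols)
  pats <- unique(measurements$patient_id)
  readers <- unique(measurements$reader_id)
  if (length(readers) < 2) stop("need at least two readers")
  interM <- matrix(NA_real_, length(pats), length(featCols))
  intraM <- matrix(NA_real_, length(pats), length(featCols))
  for (i in seq_along(pats)) {
    rows <- measurements[measurements$patient_id == pats[i], , drop = FALSE]
    K <- min(table(rows$reader_id))
    if (K < 2) stop("every reader needs >= 2 repeats per patient")
    for (j in seq_along(featCols)) {
      v <- rows[[featCols[j]]]
      byReader <- split(v, rows$reader_id)
      wvar <- vapply(byReader, var, numeric(1))
      means <- vapply(byReader, mean, numeric(1))
      intra <- mean(wvar)
      inter <- max(0, var(means) - intra / K)
      intraM[i, j] <- intra
      interM[i, j] <- inter
    }
  }
  intraMean <- colMeans(intraM)
  interMean <- colMeans(interM)
  ratios <- ifelse(intraMean == 0 & interMean == 0, 0,
                   interMean / intraMean)
  names(ratios) <- featCols
  inf <- !is.finite(ratios)
  if (any(inf))
    warning(sum(inf), " features with zero intrareader variance excluded")
  fin <- ratios[!inf]
  summ <- if (length(fin))
    list(mean = mean(fin), median = median(fin), range = range(fin),
         sd = sd(fin))
  else
    list(mean = NA_real_, median = NA_real_,
         range = c(NA_real_, NA_real_), sd = NA_real_)
  list(ratios = ratios,
       report = round(ratios, 4),
       summary = summ,
       excluded = names(ratios)[inf])
}

#' Build a reader-agreement report
#'
#' Combines per-feature Pearson correlation, Wilcoxon signed-rank p-values
#' (first repeat of each reader) and inter/intrareader variance ratios, and
#' counts features with `r > rThreshold` per feature class (first-order vs
#' GLCM) and block.
#'
#' @param measurements Long-format table as in [varianceRatio()].
#' @param rThreshold Correlation threshold for the counts (default 0.8).
#' @return An [AgreementReport-class].
#' @export
agreementReport <- function(measurements, rThreshold = 0.8) {
  keyCols <- c("patient_id", "reader_id", "repeat_index")
  featCols <- setdiff(names(measurements), keyCols)
  readers <- sort(unique(measurements$reader_id))
  first <- function(r) {
    rows <- measurements[measurements$reader_id == r &
                           measurements$repeat_index ==
                           min(measurements$repeat_index), , drop = FALSE]
    rows <- rows[order(rows$patient_id), , drop = FALSE]
    as.matrix(rows[, featCols, drop = FALSE])
  }
  t1 <- first(readers[1]); t2 <- first(readers[2])
  r <- pearsonPerFeature(t1, t2)
  p <- wilcoxonPerFeature(t1, t2)
  vr <- varianceRatio(measurements)
  pf <- data.frame(feature = featCols, pearson_r = as.numeric(r),
                   wilcoxon_p = as.numeric(p),
                   variance_ratio = as.numeric(vr$report),
                   stringsAsFactors = FALSE)
  cls <- ifelse(grepl("(^|\\.)fo_", featCols), "first_order", "glcm")
  block <- sub("^([^.]+\\.[^.]+)\\..*$", "\\1", featCols)
  block[block == featCols] <- "all"
  counts <- do.call(rbind, lapply(split(seq_along(featCols),
                                        paste(cls, block, sep = "|")),
    function(idx) {
      key <- strsplit(paste(cls[idx[1]], block[idx[1]], sep = "|"),
                      "\\|")[[1]]
      data.frame(class = key[1], block = key[2], n = length(idx),
                 n_high_r = sum(r[idx] > rThreshold, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
  rownames(counts) <- NULL
  new("AgreementReport", perFeature = pf, summary = vr$summary,
      counts = counts)
}
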