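#' Univariate AUC of a single feature
#'
#' AUC is computed from the Mann-Whitney U statistic (ties count one half),
#' oriented as `max(AUC, 1 - AUC)` so that discriminative features score
#' high regardless of effect direction. The p-value is the two-sided
#' normal-approximated Mann-Whitney (Wilcoxon rank-sum) test with tie
#' correction.
#'
#' @param values Numeric feature values, one per patient.
#' @param labels Binary labels (1 = positive class); both classes must be
#'   present with at least 2 patients each.
#' @return Named numeric `c(auc = , p = )`.
#' @export
featureAUC <- function(values, labels) {
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 < 2 || n0 < 2)
    stop("both classes must be present with at least 2 patients")
  r <- rank(values)
  u <- sum(r[labels == 1]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  p <- suppressWarnings(
    wilcox.test(values[labels == 1], values[labels == 0],
                exact = FALSE, correct = TRUE)$p.value)
  c(auc = max(auc, 1 - auc), p = p)
}

#' Screen features by univariate AUC on train and test sets
#'
#' A feature passes when its oriented AUC reaches `aucFloor` in both the
#' training and the testing set and its training-set rank-sum p-value is
#' below `pCeiling`. Features that are missing (or constant) in a set are
#' excluded pairwise, never whole patients.
#'
#' @param train,test Feature tables: features-by-patients matrices, or
#'   `SummarizedExperiment`s with assay `"features"` and a `pcr` column.
#' @param trainLabels,testLabels Binary labels (ignored for
#'   `SummarizedExperiment` input).
#' @param aucFloor AUC threshold (default 0.7).
#' @param pCeiling p-value threshold (default 0.001).
#' @return `data.frame` with one row per feature: `feature`, `auc_train`,
#'   `auc_test`, `p_value`, `passes`; sorted by decreasing
#'   `min(auc_train, auc_test)`.
#' @export
screenFeatures <- function(train, test, trainLabels = NULL, testLabels = NULL,
                           aucFloor = 0.7, pCeiling = 0.001) {
  tr <- asFeatureMatrix(train, trainLabels)
  te <- asFeatureMatrix(test, testLabels)
  if (!identical(rownames(tr$x), rownames(te$x)))
    stop("train and test feature schemas differ")
  if (ncol(tr$x) == 0 || nrow(tr$x) == 0) stop("empty feature table")
  res <- t(vapply(rownames(tr$x), function(f) {
    a1 <- tryCatch(featureAUC(tr$x[f, ], tr$y), error = function(e) c(NA, NA))
    a2 <- tryCatch(featureAUC(te$x[f, ], te$y), error = function(e) c(NA, NA))
    c(a1[1], a2[1], a1[2])
  }, numeric(3)))
  out <- data.frame(feature = rownames(tr$x), auc_train = res[, 1],
                    auc_test = res[, 2], p_value = res[, 3],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$passes <- !is.na(out$auc_train) & !is.na(out$auc_test) &
    !is.na(out$p_value) & out$auc_train >= aucFloor &
    out$auc_test >= aucFloor & out$p_value < pCeiling
  out[order(-pmin(out$auc_train, out$auc_test)), , drop = FALSE]
}

## Coerce a SummarizedExperiment or matrix (+ labels) to list(x, y).
asFeatureMatrix <- function(table, labels = NULL) {
  if (is(table, "SummarizedExperiment")) {
    x <- SummarizedExperiment::assay(table, "features")
    y <- SummarizedExperiment::colData(table)$pcr
  } else {
    x <- as.matrix(table)
    y <- labels
  }
  if (is.null(y)) stop("labels are required")
  list(x = x, y = as.integer(y))
}
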