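#' Stratified train/test split
#'
#' Splits patients by label stratum at the given train fraction; the
#' per-stratum training count is the nearest integer with halves rounded up
#' (`floor(n * fraction + 0.5)`) — the convention that turns 78/85 strata
#' into a 52+57 = 109 train and 26+28 = 54 test split at 2:1.
#'
#' @param labels Binary label vector (>= 2 patients per class).
#' @param trainFraction Training fraction (default 2/3 for a 2:1 ratio).
#' @param seed Integer seed; membership is deterministic given it.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratifiedSplit <- function(labels, trainFraction = 2 / 3, seed = 1L) {
  labels <- as.integer(labels)
  if (any(table(labels) < 2) || length(unique(labels)) < 2)
    stop("each class needs at least 2 members")
  train <- integer(0)
  withSeed(stableHash(seed, "split"), {
    for (g in sort(unique(labels))) {
      idx <- which(labels == g)
      nTrain <- floor(length(idx) * trainFraction + 0.5)
      train <- c(train, sample(idx, nTrain))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

## Patients-x-features design matrix from a feature table; drops features
## with missing values (feature-wise) and constant columns.
designMatrix <- function(se, ids = NULL, warnDropped = TRUE) {
  d <- asFeatureMatrix(se)
  x <- t(d$x)
  y <- d$y
  if (!is.null(ids)) { x <- x[ids, , drop = FALSE]; y <- y[ids] }
  list(x = x, y = y)
}

dropDegenerate <- function(xTrain, xTest = NULL, warn = TRUE) {
  bad <- apply(xTrain, 2, function(v) anyNA(v) || var(v) == 0)
  if (!is.null(xTest))
    bad <- bad | apply(xTest, 2, anyNA)
  if (all(bad)) stop("no usable (finite, non-constant) features remain")
  if (any(bad) && warn)
    warning(sum(bad), " degenerate or incomplete features dropped")
  list(train = xTrain[, !bad, drop = FALSE],
       test = if (!is.null(xTest)) xTest[, !bad, drop = FALSE])
}

#' Elastic-net logistic regression with CV-tuned penalty
#'
#' Fits penalized logistic regression over a grid of mixing parameters
#' `alpha` in {0.1, ..., 1.0} and a regularization path, choosing the
#' `(alpha, lambda)` pair that maximizes mean cross-validated AUC
#' (fivefold by default, folds stratified by label and shared across the
#' alpha grid). Features are standardized internally on training
#' statistics. Constant features are dropped with a warning.
#'
#' @param x Patients-by-features numeric matrix (no missing values).
#' @param y Binary labels.
#' @param cvFolds Folds for hyperparameter selection (default 5); each
#'   class must have at least this many patients.
#' @param alphaGrid Mixing-parameter grid.
#' @param nLambda Length of the per-alpha regularization path.
#' @param thresh Coordinate-descent convergence tolerance passed to
#'   `glmnet` (default 1e-5; selection and CV AUC are insensitive to a
#'   tighter tolerance at these problem sizes).
#' @param seed Integer seed controlling fold assignment.
#' @return An object of class `elasticNetFit`: the winning `cv.glmnet`
#'   fit plus `alpha`, `lambda`, `cvAUC`, `selected` (names of
#'   nonzero-coefficient features) and `coefficients`.
#' @export
fitElasticNet <- function(x, y, cvFolds = 5L, alphaGrid = seq(0.1, 1, 0.1),
                          nLambda = 100L, thresh = 1e-5, seed = 1L) {
  y <- as.integer(y)
  if (min(table(y)) < cvFolds)
    stop("need at least cvFolds patients per class")
  keep <- apply(x, 2, function(v) !anyNA(v) && var(v) > 0)
  if (!any(keep)) stop("all features are constant or incomplete")
  if (any(!keep)) warning(sum(!keep), " constant/incomplete features dropped")
  x <- x[, keep, drop = FALSE]
  foldid <- integer(length(y))
  withSeed(stableHash(seed, "enet-folds"), {
    for (g in unique(y)) {
      idx <- which(y == g)
      foldid[idx] <- sample(rep_len(seq_len(cvFolds), length(idx)))
    }
  })
  best <- NULL
  for (a in alphaGrid) {
    cvfit <- glmnet::cv.glmnet(x, y, family = "binomial",
                               type.measure = "auc", foldid = foldid,
                               alpha = a, nlambda = nLambda,
                               thresh = thresh, standardize = TRUE)
    ## cv.glmnet falls back to deviance when folds are too small for AUC;
    ## orient the criterion so "larger is better" either way
    score <- if (identical(cvfit$name, c(auc = "AUC")) ||
                 grepl("AUC", cvfit$name[1])) cvfit$cvm else -cvfit$cvm
    i <- which.max(score)
    if (is.null(best) || score[i] > best$score) {
      best <- list(cvfit = cvfit, alpha = a, lambda = cvfit$lambda[i],
                   cvAUC = cvfit$cvm[i], score = score[i])
    }
  }
  beta <- as.matrix(coef(best$cvfit, s = best$lambda))
  nz <- beta[-1, 1]
  sel <- names(nz)[nz != 0]
  structure(list(cvfit = best$cvfit, alpha = best$alpha,
                 lambda = best$lambda, cvAUC = best$cvAUC,
                 features = colnames(x), selected = sel,
                 coefficients = setNames(beta[, 1], rownames(beta)),
                 learner = "elastic_net_logistic"),
            class = "elasticNetFit")
}

#' @export
predict.elasticNetFit <- function(object, newx, ...) {
  newx <- newx[, object$features, drop = FALSE]
  as.numeric(predict(object$cvfit, newx = newx, s = object$lambda,
                     type = "response"))
}

#' Support-vector-machine comparator
#'
#' Linear or RBF-kernel SVM with the cost parameter tuned by the same
#' fivefold stratified CV-AUC protocol as the elastic net; class
#' probabilities are exposed for ROC analysis.
#'
#' @param x Patients-by-features matrix.
#' @param y Binary labels.
#' @param kernel `"linear"` or `"rbf"`.
#' @param cvFolds CV folds for tuning.
#' @param costGrid Candidate cost values.
#' @param seed Integer seed.
#' @return An object of class `svmFit` with a `predict` method returning
#'   positive-class probabilities.
#' @export
fitSVM <- function(x, y, kernel = c("linear", "rbf"), cvFolds = 5L,
                   costGrid = c(0.1, 1, 10), seed = 1L) {
  kernel <- match.arg(kernel)
  y <- as.integer(y)
  if (min(table(y)) < cvFolds)
    stop("need at least cvFolds patients per class")
  keep <- apply(x, 2, function(v) !anyNA(v) && var(v) > 0)
  if (any(!keep)) warning(sum(!keep), " constant/incomplete features dropped")
  x <- x[, keep, drop = FALSE]
  ekernel <- if (kernel == "linear") "linear" else "radial"
  foldid <- integer(length(y))
  withSeed(stableHash(seed, "svm-folds"), {
    for (g in unique(y)) {
      idx <- which(y == g)
      foldid[idx] <- sample(rep_len(seq_len(cvFolds), length(idx)))
    }
  })
  yf <- factor(y, levels = c(0, 1))
  cvAUC <- vapply(costGrid, function(cost) {
    probs <- rep(NA_real_, length(y))
    for (f in seq_len(cvFolds)) {
      tr <- foldid != f
      fit <- e1071::svm(x[tr, , drop = FALSE], yf[tr], kernel = ekernel,
                        cost = cost, probability = TRUE, scale = TRUE)
      pr <- predict(fit, x[!tr, , drop = FALSE], probability = TRUE)
      probs[!tr] <- attr(pr, "probabilities")[, "1"]
    }
    as.numeric(pROC::auc(pROC::roc(y, probs, levels = c(0, 1),
                                   direction = "<", quiet = TRUE)))
  }, numeric(1))
  cost <- costGrid[which.max(cvAUC)]
  fit <- e1071::svm(x, yf, kernel = ekernel, cost = cost,
                    probability = TRUE, scale = TRUE)
  structure(list(fit = fit, features = colnames(x), cost = cost,
                 cvAUC = max(cvAUC),
                 learner = paste0("svm_", kernel)),
            class = "svmFit")
}

#' @export
predict.svmFit <- function(object, newx, ...) {
  newx <- newx[, object$features, drop = FALSE]
  pr <- predict(object$fit, newx, probability = TRUE)
  as.numeric(attr(pr, "probabilities")[, "1"])
}

#' Evaluate a fitted model on a held-out test set
#'
#' Test AUC comes from predicted probabilities (reported as-is, not
#' reoriented), accuracy from thresholding probability at 0.5, the 95% AUC
#' confidence interval from DeLong's method, and the p-value from the
#' DeLong variance under the null AUC = 0.5.
#'
#' @param model An `elasticNetFit` or `svmFit`.
#' @param xTrain,yTrain Training design matrix and labels (for the
#'   training AUC).
#' @param xTest,yTest Held-out design matrix and labels (both classes must
#'   be present).
#' @param spec Optional list describing the model (stored in the result).
#' @return A [ModelResult-class].
#' @export
evaluateHoldout <- function(model, xTrain, yTrain, xTest, yTest,
                            spec = list()) {
  yTest <- as.integer(yTest)
  if (length(unique(yTest)) < 2) stop("test set contains a single class")
  pTrain <- predict(model, xTrain)
  pTest <- predict(model, xTest)
  rTrain <- pROC::roc(as.integer(yTrain), pTrain, levels = c(0, 1),
                      direction = "<", quiet = TRUE)
  rTest <- pROC::roc(yTest, pTest, levels = c(0, 1),
                     direction = "<", quiet = TRUE)
  aucTest <- as.numeric(pROC::auc(rTest))
  ci <- as.numeric(pROC::ci.auc(rTest, method = "delong"))[c(1, 3)]
  v <- pROC::var(rTest, method = "delong")
  p <- if (v > 0) 2 * pnorm(-abs((aucTest - 0.5) / sqrt(v))) else 0
  sel <- if (inherits(model, "elasticNetFit")) model$selected
         else model$features
  coefs <- if (inherits(model, "elasticNetFit"))
    model$coefficients[model$selected] else numeric(0)
  new("ModelResult", spec = spec, selectedFeatures = sel,
      coefficients = coefs,
      aucTrain = as.numeric(pROC::auc(rTrain)), aucTest = aucTest,
      accuracyTest = mean((pTest >= 0.5) == (yTest == 1)),
      aucCI = ci, pValue = p)
}

#' Pooled k-fold cross-validated AUC
#'
#' Unstratified, seed-controlled folds; out-of-fold predicted
#' probabilities are pooled into a single AUC. If a fold leaves the
#' training data with one class, the data are refolded under a new derived
#' seed (with a message).
#'
#' @param x Patients-by-features matrix.
#' @param y Binary labels.
#' @param folds Number of folds (default 3).
#' @param learner `"elastic_net"`, `"svm_linear"` or `"svm_rbf"`.
#' @param seed Integer seed.
#' @param ... Passed to the learner's fitting function.
#' @return List with `auc`, pooled `probabilities`, and `foldid`.
#' @export
crossValidate <- function(x, y, folds = 3L, learner = "elastic_net",
                          seed = 1L, ...) {
  y <- as.integer(y)
  n <- length(y)
  if (n < folds) stop("need at least `folds` patients")
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    foldid <- withSeed(stableHash(seed, "cv", attempt),
                       sample(rep_len(seq_len(folds), n)))
    if (all(vapply(seq_len(folds), function(f)
      length(unique(y[foldid != f])) == 2 && min(table(y[foldid != f])) >= 2,
      logical(1)))) break
    if (attempt > 25L) stop("could not find folds with both classes")
    message("refolding: a fold left the training data single-class")
  }
  probs <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    tr <- foldid != f
    fit <- switch(learner,
      elastic_net = fitElasticNet(x[tr, , drop = FALSE], y[tr],
                                  seed = stableHash(seed, "fold", f), ...),
      svm_linear = fitSVM(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                          seed = stableHash(seed, "fold", f), ...),
      svm_rbf = fitSVM(x[tr, , drop = FALSE], y[tr], kernel = "rbf",
                       seed = stableHash(seed, "fold", f), ...),
      stop("unknown learner: ", learner))
    probs[!tr] <- predict(fit, x[!tr, , drop = FALSE])
  }
  r <- pROC::roc(y, probs, levels = c(0, 1), direction = "<", quiet = TRUE)
  list(auc = as.numeric(pROC::auc(r)), probabilities = probs, foldid = foldid)
}

#' Enumerate the multivariate model grid
#'
#' The default grid holds one model per feature family (each raw timepoint
#' and each delta block, DCE and DWI combined) plus any configured
#' multi-family combinations; the combination of a late timepoint with its
#' absolute change from baseline is included by default. The grid is an
#' explicit list and serializes to JSON.
#'
#' @param blocks Available block labels (default: 3 timepoints, and both
#'   delta modes over the 3 ordered pairs).
#' @param sequences Sequences entering every model (default both).
#' @param extraCombos List of character vectors of blocks to combine.
#' @param learner Learner name stored in each spec.
#' @return List of model specs (`family`, `sequences`, `learner`,
#'   `cvFoldsHyper`, `evalMode`).
#' @export
enumerateModelGrid <- function(blocks = c("BL", "C2", "C4",
                                          "AD_C2_BL", "AD_C4_BL", "AD_C4_C2",
                                          "RD_C2_BL", "RD_C4_BL", "RD_C4_C2"),
                               sequences = c("DCE", "DWI"),
                               extraCombos = list(c("C4", "AD_C4_BL")),
                               learner = "elastic_net_logistic") {
  fams <- c(as.list(blocks), extraCombos)
  lapply(fams, function(f)
    list(family = as.character(f), sequences = sequences, learner = learner,
         cvFoldsHyper = 5L, evalMode = "holdout"))
}

#' Fit and evaluate one model spec on a feature table
#'
#' Subsets the requested feature blocks, drops incomplete or constant
#' features, fits the spec's learner on the training patients and
#' evaluates on the held-out patients.
#'
#' @param se Feature table from [assembleFeatureTable()].
#' @param split A [stratifiedSplit()] result.
#' @param spec One entry of [enumerateModelGrid()].
#' @param seed Integer seed.
#' @param ... Passed to the learner.
#' @return A [ModelResult-class].
#' @export
fitModelSpec <- function(se, split, spec, seed = 1L, ...) {
  sub <- selectBlocks(se, spec$family, spec$sequences)
  d <- designMatrix(sub)
  xTr <- d$x[split$train, , drop = FALSE]
  xTe <- d$x[split$test, , drop = FALSE]
  cln <- dropDegenerate(xTr, xTe, warn = FALSE)
  yTr <- d$y[split$train]; yTe <- d$y[split$test]
  model <- switch(spec$learner,
    elastic_net_logistic = fitElasticNet(cln$train, yTr,
                                         cvFolds = spec$cvFoldsHyper %||% 5L,
                                         seed = seed, ...),
    svm_linear = fitSVM(cln$train, yTr, kernel = "linear", seed = seed, ...),
    svm_rbf = fitSVM(cln$train, yTr, kernel = "rbf", seed = seed, ...),
    stop("unknown learner: ", spec$learner))
  evaluateHoldout(model, cln$train, yTr, cln$test, yTe, spec = spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
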