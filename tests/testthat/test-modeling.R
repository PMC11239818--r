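test_that("stratified split reproduces the 109/54 arithmetic exactly", {
  y <- c(rep(1, 78), rep(0, 85))
  sp <- stratifiedSplit(y, seed = 123)
  expect_length(sp$train, 109)
  expect_length(sp$test, 54)
  expect_equal(sum(y[sp$train] == 1), 52)
  expect_equal(sum(y[sp$train] == 0), 57)
  expect_equal(sum(y[sp$test] == 1), 26)
  expect_equal(sum(y[sp$test] == 0), 28)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, stratifiedSplit(y, seed = 123))

  sp2 <- stratifiedSplit(rep(0:1, each = 3))
  expect_equal(length(sp2$train), 4)
  expect_error(stratifiedSplit(c(0, 1, 1)), "class")
})

test_that("elastic net recovers a planted separating feature", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 109
    y <- c(rep(0, 57), rep(1, 52))
    x <- cbind(planted = y * 3 + rnorm(n, 0, 0.5),
               matrix(rnorm(50 * n), n,
                      dimnames = list(NULL, sprintf("noise%02d", 1:50))))
    fit <- fitElasticNet(x, y, alphaGrid = c(0.1, 0.5, 1), nLambda = 50,
                         seed = seed)
    hits <- hits + ("planted" %in% fit$selected)
  }
  expect_gte(hits, 18)
})

test_that("elastic net on pure noise has chance-level CV AUC", {
  aucs <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 60
    y <- rep(0:1, each = n / 2)
    x <- matrix(rnorm(30 * n), n,
                dimnames = list(NULL, sprintf("f%02d", 1:30)))
    fitElasticNet(x, y, cvFolds = 3, alphaGrid = c(0.1, 0.5, 1),
                  nLambda = 50, seed = seed)$cvAUC
  }, numeric(1))
  expect_gte(mean(aucs), 0.35)
  expect_lte(mean(aucs), 0.65)
})

test_that("a huge lasso penalty zeroes every coefficient", {
  set.seed(4)
  x <- matrix(rnorm(40 * 10), 40)
  y <- rep(0:1, 20)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1)
  beta <- as.matrix(coef(fit, s = max(fit$lambda) * 10))
  expect_true(all(beta[-1, ] == 0))
})

test_that("holdout evaluation computes AUC, accuracy, DeLong CI and p", {
  set.seed(6)
  n <- 80
  y <- rep(0:1, each = n / 2)
  x <- cbind(sig = y * 4 + rnorm(n, 0, 0.4),
             matrix(rnorm(5 * n), n, dimnames = list(NULL, paste0("n", 1:5))))
  sp <- stratifiedSplit(y, seed = 2)
  fit <- fitElasticNet(x[sp$train, ], y[sp$train], alphaGrid = c(0.5, 1),
                       seed = 2)
  res <- evaluateHoldout(fit, x[sp$train, ], y[sp$train],
                         x[sp$test, ], y[sp$test])
  expect_s4_class(res, "ModelResult")
  expect_gt(res@aucTest, 0.9)
  expect_gte(res@aucTest, res@aucCI[1])
  expect_lte(res@aucTest, res@aucCI[2])
  expect_lt(res@pValue, 0.05)
  expect_error(evaluateHoldout(fit, x, y, x[1:3, ], c(1, 1, 1)),
               "single class")
})

test_that("perfect and anti-perfect scores give AUC 1 and 0", {
  y <- rep(0:1, each = 10)
  r <- pROC::roc(y, as.numeric(y), levels = c(0, 1), direction = "<",
                 quiet = TRUE)
  expect_equal(as.numeric(pROC::auc(r)), 1)
  r2 <- pROC::roc(y, -as.numeric(y), levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  expect_equal(as.numeric(pROC::auc(r2)), 0)
})

test_that("DeLong variance matches the placement-value formula by hand", {
  y <- c(0, 0, 0, 1, 1, 1)
  s <- c(0.1, 0.4, 0.35, 0.8, 0.3, 0.9)
  r <- pROC::roc(y, s, levels = c(0, 1), direction = "<", quiet = TRUE)
  pos <- s[y == 1]; neg <- s[y == 0]
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  V10 <- vapply(pos, function(a) mean(psi(a, neg)), numeric(1))
  V01 <- vapply(neg, function(b) mean(psi(pos, b)), numeric(1))
  vHand <- var(V10) / length(pos) + var(V01) / length(neg)
  expect_equal(as.numeric(pROC::var(r, method = "delong")), vHand,
               tolerance = 1e-12)
  expect_equal(as.numeric(pROC::auc(r)), bruteAUC(s, y))
})

test_that("3-fold CV pools out-of-fold probabilities deterministically", {
  set.seed(9)
  n <- 66
  y <- rep(0:1, each = n / 2)
  x <- cbind(sig = y * 2 + rnorm(n, 0, 0.7),
             matrix(rnorm(10 * n), n,
                    dimnames = list(NULL, paste0("n", 1:10))))
  cv1 <- crossValidate(x, y, folds = 3, seed = 7, cvFolds = 3L,
                       alphaGrid = c(0.5, 1), nLambda = 50)
  cv2 <- crossValidate(x, y, folds = 3, seed = 7, cvFolds = 3L,
                       alphaGrid = c(0.5, 1), nLambda = 50)
  expect_identical(cv1, cv2)
  expect_gt(cv1$auc, 0.7)
  expect_equal(sort(as.integer(table(
    crossValidate(matrix(rnorm(163 * 2), 163,
                         dimnames = list(NULL, c("a", "b"))),
                  rep_len(0:1, 163), folds = 3, learner = "svm_linear",
                  seed = 1, cvFolds = 2L)$foldid))), c(54, 54, 55))
})

test_that("SVM comparators run and a linear signal favors the elastic net", {
  set.seed(10)
  n <- 60
  y <- rep(0:1, each = n / 2)
  x <- cbind(sig = y * 5 + rnorm(n, 0, 0.3),
             matrix(rnorm(5 * n), n, dimnames = list(NULL, paste0("n", 1:5))))
  svmL <- fitSVM(x, y, "linear", cvFolds = 3, seed = 1)
  svmR <- fitSVM(x, y, "rbf", cvFolds = 3, seed = 1)
  pr <- predict(svmL, x)
  rocL <- pROC::roc(y, pr, levels = c(0, 1), direction = "<", quiet = TRUE)
  expect_equal(as.numeric(pROC::auc(rocL)), 1)
  expect_true(is.numeric(predict(svmR, x)))

  # on a linear planted signal, elastic-net test AUC is not materially
  # worse than SVM-RBF
  diffs <- vapply(1:6, function(seed) {
    set.seed(seed + 100)
    n <- 90
    y <- rep(0:1, each = n / 2)
    x <- cbind(sig = y * 1.5 + rnorm(n),
               matrix(rnorm(20 * n), n,
                      dimnames = list(NULL, sprintf("n%02d", 1:20))))
    sp <- stratifiedSplit(y, seed = seed)
    en <- fitElasticNet(x[sp$train, ], y[sp$train],
                        alphaGrid = c(0.1, 0.5, 1), nLambda = 50,
                        seed = seed)
    sv <- fitSVM(x[sp$train, ], y[sp$train], "rbf", seed = seed)
    rocA <- function(p) as.numeric(pROC::auc(pROC::roc(
      y[sp$test], p, levels = c(0, 1), direction = "<", quiet = TRUE)))
    rocA(predict(en, x[sp$test, ])) - rocA(predict(sv, x[sp$test, ]))
  }, numeric(1))
  expect_gte(mean(diffs), -0.05)
})

test_that("the model grid enumerates families and serializes", {
  grid <- enumerateModelGrid()
  expect_gte(length(grid), 9)
  fams <- vapply(grid, function(g) paste(g$family, collapse = "+"), "")
  expect_true("RD_C2_BL" %in% fams)
  expect_true("C4+AD_C4_BL" %in% fams)   # combination spec parses

  json <- jsonlite::toJSON(grid, auto_unbox = TRUE)
  back <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  expect_equal(length(back), length(grid))
  expect_equal(unlist(back[[1]]$family), grid[[1]]$family)
})
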