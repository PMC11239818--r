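test_that("first-order features match hand computation on 1..100", {
  fo <- firstOrderFeatures(1:100)
  expect_length(fo, 10)
  expect_equal(unname(fo["fo_minimum"]), 1)
  expect_equal(unname(fo["fo_maximum"]), 100)
  expect_equal(unname(fo["fo_mean"]), 50.5)
  expect_equal(unname(fo["fo_sd"]), sd(1:100))
  expect_equal(unname(fo["fo_p5"]), 5.95)     # linear interpolation
  expect_equal(unname(fo["fo_p1"]), 1.99)
  expect_equal(unname(fo["fo_p95"]), 95.05)
  expect_equal(unname(fo["fo_p99"]), 99.01)
  # uniform distribution: skewness 0, excess kurtosis near -1.2
  expect_equal(unname(fo["fo_skewness"]), 0, tolerance = 1e-12)
  x <- 1:100; m <- mean(x)
  expect_equal(unname(fo["fo_kurtosis"]),
               mean((x - m)^4) / mean((x - m)^2)^2 - 3)
})

test_that("first-order features handle constant and empty input", {
  fo <- firstOrderFeatures(rep(3.5, 20))
  expect_equal(unname(fo[c("fo_minimum", "fo_maximum", "fo_mean", "fo_p1",
                           "fo_p99")]), rep(3.5, 5))
  expect_equal(unname(fo[c("fo_sd", "fo_skewness", "fo_kurtosis")]),
               c(0, 0, 0))
  expect_true(all(is.na(firstOrderFeatures(numeric(0)))))
  # normal sample: excess kurtosis near 0
  set.seed(1)
  expect_lt(abs(firstOrderFeatures(rnorm(2e4))["fo_kurtosis"]), 0.1)
})

test_that("quantization spans the VOI range with fixed bin count", {
  vol <- array(0, dim = c(8, 4, 1))
  vol[, , 1] <- matrix(0:31, 8, 4)
  voi <- VOIMask(array(TRUE, dim = dim(vol)))
  q <- quantizeVolume(vol, voi, quantizationParams(32))
  expect_equal(as.vector(q), as.vector(vol) + 1)

  constQ <- quantizeVolume(array(5, dim = c(4, 4, 1)),
                           VOIMask(array(TRUE, c(4, 4, 1))))
  expect_true(all(constQ == 1))
  expect_true(attr(constQ, "constant"))

  set.seed(2)
  vol2 <- array(rnorm(64), dim = c(4, 4, 4))
  q2 <- quantizeVolume(vol2, VOIMask(array(TRUE, c(4, 4, 4))),
                       quantizationParams(8))
  expect_true(all(q2 >= 1 & q2 <= 8))
  expect_equal(max(q2), 8)  # maximum maps to the top level
})

test_that("GLCM on the 2x2 hand example matches enumeration", {
  q <- array(NA_integer_, dim = c(2, 2, 1))
  q[, , 1] <- matrix(c(1, 1, 1, 2), 2, 2)   # [[1,1],[1,2]] by rows
  P <- glcmMatrix(q, 1, c(1, 0), symmetric = TRUE, nLevels = 2)
  expect_equal(P[1, 1], 0.5)
  expect_equal(P[1, 2], 0.25)
  expect_equal(P[2, 1], 0.25)
  expect_equal(P[2, 2], 0)
  s <- glcmStatistics(P)
  expect_equal(unname(s["contrast"]), 0.5)

  # constant VOI: single nonzero entry at (1,1)
  qc <- array(1L, dim = c(3, 3, 1))
  Pc <- glcmMatrix(qc, 1, c(0, 1), nLevels = 4)
  expect_equal(Pc[1, 1], 1)
  sc <- glcmStatistics(Pc)
  expect_equal(unname(sc["contrast"]), 0)
  expect_equal(unname(sc["joint_energy"]), 1)
  expect_equal(unname(sc["joint_entropy"]), 0)
  expect_equal(unname(sc["maximum_probability"]), 1)

  # uniform matrix over L levels: joint entropy 2*log2(L)
  L <- 4
  Pu <- matrix(1 / L^2, L, L)
  expect_equal(unname(glcmStatistics(Pu)["joint_entropy"]), 2 * log2(L))
})

test_that("all 25 GLCM statistics at all 12 offsets match brute force", {
  cfgG <- glcmConfig()
  for (seed in 1:4) {
    q <- randomQuantized(c(6, 6, 3), L = 5, seed = seed)
    for (d in cfgG$distances) {
      for (dir in cfgG$directions) {
        P <- glcmMatrix(q, d, dir, symmetric = TRUE, nLevels = 5)
        B <- bruteGLCM(q, d, dir, L = 5)
        if (is.null(B)) {
          expect_true(isTRUE(attr(P, "empty")))
          next
        }
        expect_equal(unclass(P)[1:25], unclass(B)[1:25], tolerance = 1e-12)
        expect_equal(sum(P), 1, tolerance = 1e-12)
        expect_equal(P, t(P), ignore_attr = TRUE)
        s <- glcmStatistics(P)
        b <- bruteGLCMStats(B)
        expect_equal(unname(s[names(b)]), unname(b), tolerance = 1e-10)
      }
    }
  }
})

test_that("feature vectors have the contracted schema and invariances", {
  cfg <- smallCohortConfig(n = 2, seed = 6)
  cl <- generateCohort(cfg)
  st <- simulateStudy(cl[1, ], "BL", cfg)
  voi <- st@metadata$truthMask
  fv <- extractFeatureVector(st, voi, "DCE")

  expect_length(fv, 310)
  expect_equal(sum(grepl("^fo_", names(fv))), 10)
  expect_equal(sum(grepl("^glcm_", names(fv))), 300)
  expect_identical(names(fv), radiomicFeatureNames())
  expect_identical(as.numeric(fv),
                   as.numeric(extractFeatureVector(st, voi, "DCE")))

  # translating volume and VOI together by whole voxels leaves features
  # unchanged
  shift <- function(a) {
    out <- array(0, dim = dim(a))
    out[2:dim(a)[1], 2:dim(a)[2], ] <-
      a[1:(dim(a)[1] - 1), 1:(dim(a)[2] - 1), ]
    out
  }
  m <- maskArray(voi)
  stS <- MRIStudy(patientId(st), "BL",
                  dceSubtraction = shift(st@dceSubtraction),
                  voxelSpacing = voxelSpacing(st))
  voiS <- VOIMask(shift(m) > 0.5)
  fvS <- extractFeatureVector(stS, voiS, "DCE")
  expect_equal(as.numeric(fvS), as.numeric(fv), tolerance = 1e-10)

  # intensity shift: location features shift, shape/texture invariant
  stC <- MRIStudy(patientId(st), "BL",
                  dceSubtraction = st@dceSubtraction + 7,
                  voxelSpacing = voxelSpacing(st))
  fvC <- extractFeatureVector(stC, voi, "DCE")
  loc <- c("fo_minimum", "fo_maximum", "fo_mean", "fo_p1", "fo_p5",
           "fo_p95", "fo_p99")
  expect_equal(as.numeric(fvC[loc]), as.numeric(fv[loc]) + 7,
               tolerance = 1e-9)
  rest <- setdiff(names(fv), loc)
  expect_equal(as.numeric(fvC[rest]), as.numeric(fv[rest]),
               tolerance = 1e-9)

  # empty VOI: all-missing vector, not an error
  fvE <- extractFeatureVector(
    st, VOIMask(array(FALSE, dim = dim(m)), tumorBed = TRUE), "DCE")
  expect_true(all(is.na(fvE)))
  expect_true(attr(fvE, "emptyVOI"))
})

test_that("GLCM contrast increases with texture heterogeneity", {
  # smooth deterministic ramp plus white noise of growing s.d.: because
  # quantization is range-relative, contrast must rise with the share of
  # uncorrelated (heterogeneous) signal
  set.seed(77)
  d <- c(20, 20, 4)
  base <- array(0, dim = d)
  for (k in 1:d[3])
    base[, , k] <- outer(sin(seq_len(d[1]) / 5), cos(seq_len(d[2]) / 6), `+`)
  noise <- array(rnorm(prod(d)), dim = d)
  voi <- VOIMask(array(TRUE, dim = d))
  cfgG <- glcmConfig()
  contrasts <- vapply(seq(0.2, 2.9, length.out = 10), function(s) {
    vol <- 3 * base + s * noise
    q <- quantizeVolume(vol, voi, quantizationParams(16))
    offs <- numeric(0)
    for (dd in cfgG$distances)
      for (dir in cfgG$directions)
        offs <- c(offs, glcmStatistics(
          glcmMatrix(q, dd, dir, nLevels = 16), "contrast"))
    mean(offs)
  }, numeric(1))
  expect_true(all(diff(contrasts) > 0))
})
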