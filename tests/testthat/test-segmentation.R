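# Two-level phantom: bright tumor block inside a dim rim, wrapped in a
# generous rough contour.
makePhantom <- function() {
  vol <- array(0, dim = c(16, 16, 6))
  rough <- array(FALSE, dim = dim(vol))
  rough[4:13, 4:13, 2:5] <- TRUE
  vol[rough] <- 10                               # rim
  tumor <- array(FALSE, dim = dim(vol))
  tumor[6:11, 6:11, 3:4] <- TRUE
  vol[tumor] <- 100
  list(vol = vol, rough = VOIMask(rough), tumor = tumor)
}

test_that("Otsu thresholding recovers a two-level phantom exactly", {
  ph <- makePhantom()
  voi <- thresholdSegment(ph$vol, ph$rough, segmentationParams())
  expect_identical(maskArray(voi), ph$tumor)

  # brute-force Otsu over candidate cuts agrees with the internal rule
  vals <- ph$vol[maskArray(ph$rough)]
  cuts <- sort(unique(vals))
  between <- vapply(head(cuts, -1), function(cut) {
    lo <- vals[vals <= cut]; hi <- vals[vals > cut]
    length(lo) * length(hi) / length(vals)^2 * (mean(lo) - mean(hi))^2
  }, numeric(1))
  bruteThr <- mean(cuts[which.max(between) + 0:1])
  expect_identical(maskArray(ph$rough) & ph$vol >= bruteThr, ph$tumor)
})

test_that("segmentation degenerate cases behave as documented", {
  vol <- array(7, dim = c(16, 16, 4))
  rough <- array(FALSE, dim = dim(vol)); rough[5:10, 5:10, 2:3] <- TRUE
  out <- thresholdSegment(vol, VOIMask(rough))
  expect_identical(maskArray(out), rough)   # constant region: whole contour

  empty <- VOIMask(array(FALSE, dim = dim(vol)), tumorBed = TRUE)
  expect_identical(maskArray(thresholdSegment(vol, empty)),
                   maskArray(empty))
  expect_error(thresholdSegment(array(0, c(2, 2, 2)), VOIMask(rough)),
               "shape")
})

test_that("output is a subset of the rough mask and thresholding is monotone and idempotent", {
  set.seed(31)
  for (rep in 1:5) {
    vol <- array(rnorm(16 * 16 * 6), dim = c(16, 16, 6))
    rough <- array(runif(prod(dim(vol))) < 0.4, dim = dim(vol))
    if (!any(rough)) next
    rv <- VOIMask(rough, tumorBed = TRUE)
    params <- segmentationParams(minComponentVoxels = 1L)
    voi <- thresholdSegment(vol, rv, params)
    expect_true(all(maskArray(voi) <= rough))

    # raising the fixed quantile never grows the VOI
    sizes <- vapply(c(0.2, 0.5, 0.8), function(q)
      sum(maskArray(thresholdSegment(vol, rv,
        segmentationParams("fixed_quantile", quantile = q,
                           minComponentVoxels = 1L)))), numeric(1))
    expect_true(all(diff(sizes) <= 0))

    # idempotence: re-applying with the same threshold returns the same mask
    if (any(maskArray(voi))) {
      again <- thresholdSegment(vol, voi, params,
                                threshold = attr(voi, "threshold"))
      expect_identical(maskArray(again), maskArray(voi))
    }
  }
})

test_that("small components are pruned", {
  vol <- array(0, dim = c(16, 16, 4))
  rough <- array(TRUE, dim = dim(vol))
  vol[4:9, 4:9, 2:3] <- 100      # 72-voxel blob
  vol[14, 14, 4] <- 100          # isolated speckle
  voi <- thresholdSegment(vol, VOIMask(rough),
                          segmentationParams(minComponentVoxels = 5L))
  expect_equal(sum(maskArray(voi)), 72)
  expect_false(maskArray(voi)[14, 14, 4])
})

test_that("exclusion algebra holds", {
  set.seed(7)
  m <- array(runif(16 * 16 * 4) < 0.3, dim = c(16, 16, 4))
  ex <- array(runif(prod(dim(m))) < 0.3, dim = dim(m))
  voi <- VOIMask(m, tumorBed = !any(m))
  out <- excludeRegions(voi, ex)
  expect_identical(maskArray(out), m & !ex)
  expect_equal(sum(maskArray(out)), sum(m) - sum(m & ex))

  ident <- excludeRegions(voi, array(FALSE, dim = dim(m)))
  expect_identical(maskArray(ident), m)

  gone <- excludeRegions(voi, array(TRUE, dim = dim(m)))
  expect_true(isTumorBed(gone))
  expect_equal(sum(maskArray(gone)), 0)
})

test_that("index-lesion selection takes the largest lesion with a stable tie rule", {
  mk <- function(vox) {
    m <- array(FALSE, dim = c(12, 12, 4))
    m[vox] <- TRUE
    VOIMask(m)
  }
  lesions <- list(mk(cbind(2:4, 2, 1)), mk(cbind(2:9, 8, 2)), mk(cbind(11, 11, 3)))
  expect_identical(selectIndexLesion(lesions), lesions[[2]])
  expect_identical(selectIndexLesion(lesions[3]), lesions[[3]])

  # equal volumes: lexicographically smallest centroid wins
  a <- mk(cbind(9:10, 9, 1)); b <- mk(cbind(2:3, 2, 1))
  expect_identical(selectIndexLesion(list(a, b)), b)
  expect_identical(selectIndexLesion(list(b, a)), b)
  expect_error(selectIndexLesion(list()), "candidate")
})
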