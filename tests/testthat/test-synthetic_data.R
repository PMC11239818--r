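test_that("cohort generation hits the exact pCR count and is deterministic", {
  cfg <- cohortConfig(nPatients = 163, pcrFraction = 0.4785, seed = 42)
  cl <- generateCohort(cfg)
  expect_equal(sum(cl$pcr == 1), 78)
  expect_equal(sum(cl$pcr == 0), 85)

  cl2 <- generateCohort(cohortConfig(nPatients = 2, pcrFraction = 0.5,
                                     seed = 1))
  expect_equal(sort(cl2$pcr), c(0, 1))

  expect_identical(cl, generateCohort(cfg))
  expect_setequal(cl$clinical_stage,
                  intersect(cl$clinical_stage, c("I", "II", "III")))
  expect_true(all(cl$t_category %in% paste0("T", 1:4)))
  expect_true(all(cl$age >= 23 & cl$age <= 78))
})

test_that("adding patients does not reshuffle existing ones", {
  a <- generateCohort(cohortConfig(nPatients = 20, seed = 9))
  b <- generateCohort(cohortConfig(nPatients = 30, seed = 9))
  shared <- intersect(a$patient_id, b$patient_id)
  # covariates come from per-patient substreams, so they must agree
  expect_identical(a[a$patient_id %in% shared,
                     setdiff(names(a), "pcr")],
                   b[b$patient_id %in% shared, setdiff(names(b), "pcr")])
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohortConfig(nPatients = 1), "nPatients")
  expect_error(cohortConfig(pcrFraction = 0), "pcrFraction")
  expect_error(cohortConfig(pcrFraction = 1.2), "pcrFraction")
  expect_error(cohortConfig(gridShape = c(8, 32, 32)), "gridShape")
  expect_error(responseEffect(volumeShrinkPcr = 0.9,
                              volumeShrinkNonPcr = 0.5), "responders")
})

test_that("simulated studies are deterministic with label-driven dynamics", {
  cfg <- smallCohortConfig(n = 4, seed = 5)
  cl <- generateCohort(cfg)
  st1 <- simulateStudy(cl[1, ], "BL", cfg)
  st2 <- simulateStudy(cl[1, ], "BL", cfg)
  expect_identical(st1@dceSubtraction, st2@dceSubtraction)
  expect_identical(maskArray(st1@metadata$truthMask),
                   maskArray(st2@metadata$truthMask))

  # volumes shrink across timepoints
  vols <- vapply(c("BL", "C2", "C4"), function(tp)
    sum(maskArray(simulateStudy(cl[1, ], tp, cfg)@metadata$truthMask)),
    numeric(1))
  expect_true(vols["BL"] >= vols["C2"] && vols["C2"] >= vols["C4"])

  # DWI strictly positive where tumor present
  m <- maskArray(st1@metadata$truthMask)
  expect_true(all(st1@dwiB800[m] > 0) && all(st1@dwiB100[m] > 0))
  expect_error(simulateStudy(cl[1, ], "XX", cfg), "timepoint")
})

test_that("interior texture s.d. tracks the configured homogenize factor", {
  eff <- responseEffect(textureHomogenizePcr = 0.6,
                        textureHomogenizeNonPcr = 0.92,
                        noiseSd = 0.02, necrosisProb = 0)
  cfg <- cohortConfig(nPatients = 30, effect = eff, seed = 11,
                      timepoints = c("BL", "C2"))
  cl <- generateCohort(cfg)
  ratios <- vapply(which(cl$pcr == 1), function(i) {
    bl <- simulateStudy(cl[i, ], "BL", cfg)
    c2 <- simulateStudy(cl[i, ], "C2", cfg)
    sd(c2@dceSubtraction[maskArray(c2@metadata$truthMask)]) /
      sd(bl@dceSubtraction[maskArray(bl@metadata$truthMask)])
  }, numeric(1))
  # per-patient factor jitters around 0.6; the mean ratio must be within 10%
  expect_lt(abs(mean(ratios) - 0.6) / 0.6, 0.10)
})

test_that("pCR tumors at C2 are more homogeneous than non-pCR on average", {
  cfg <- cohortConfig(nPatients = 50, seed = 3, timepoints = c("BL", "C2"))
  cl <- generateCohort(cfg)
  sds <- vapply(seq_len(nrow(cl)), function(i) {
    st <- simulateStudy(cl[i, ], "C2", cfg)
    sd(st@dceSubtraction[maskArray(st@metadata$truthMask)])
  }, numeric(1))
  expect_lt(mean(sds[cl$pcr == 1]), mean(sds[cl$pcr == 0]))
})

test_that("a fully shrunk tumor falls back to a tumor-bed contour", {
  eff <- responseEffect(volumeShrinkPcr = 0, volumeShrinkNonPcr = 1,
                        textureHomogenizePcr = 0.5,
                        textureHomogenizeNonPcr = 1)
  cfg <- cohortConfig(nPatients = 4, pcrFraction = 0.5, effect = eff,
                      seed = 2)
  cl <- generateCohort(cfg)
  pcrRow <- cl[cl$pcr == 1, ][1, ]
  st <- simulateStudy(pcrRow, "C4", cfg)
  expect_true(st@metadata$tumorBed)
  expect_true(isTumorBed(st@metadata$truthMask))
  expect_gt(sum(maskArray(st@metadata$truthMask)), 0)  # bed, not empty
})

test_that("ADC matches the mono-exponential closed form", {
  d <- c(4, 4, 2)
  s0 <- array(2, dim = d)
  adcTrue <- array(seq(5e-4, 2e-3, length.out = prod(d)), dim = d)
  sLow <- s0 * exp(-100 * adcTrue)
  sHigh <- s0 * exp(-800 * adcTrue)
  expect_equal(computeADC(sLow, sHigh, 100, 800), adcTrue, tolerance = 1e-12)

  expect_equal(computeADC(s0, s0, 100, 800), array(0, dim = d))
  expect_equal(computeADC(array(exp(1), d), array(1, d), 100, 800)[1],
               1 / 700, tolerance = 1e-12)

  bad <- sHigh; bad[1, 1, 1] <- 0
  adc <- computeADC(sLow, bad, 100, 800)
  expect_true(is.na(adc[1, 1, 1]))
  expect_true(all(is.finite(adc[-1])))
  expect_error(computeADC(sLow, sHigh, 800, 100), "bHigh")
})

test_that("reader masks obey the jitter contract", {
  cfg <- smallCohortConfig(n = 2, seed = 8)
  cl <- generateCohort(cfg)
  st <- simulateStudy(cl[1, ], "BL", cfg)
  truth <- st@metadata$truthMask

  zero <- simulateReaderMasks(truth, 0, nReaders = 2, nRepeats = 2, seed = 1)
  expect_length(zero, 4)
  for (m in zero) expect_identical(maskArray(m), maskArray(truth))

  expect_error(simulateReaderMasks(truth, c(0.1, 0.4)), "inter >= intra")

  # Dice decreases with jitter, averaged over seeds
  meanDice <- function(j) mean(vapply(1:20, function(s) {
    ms <- simulateReaderMasks(truth, j, nReaders = 1, nRepeats = 1, seed = s)
    diceOverlap(ms[[1]], truth)
  }, numeric(1)))
  expect_gt(meanDice(0.1), meanDice(0.5))
})
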