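test_that("an empty cohort request yields an empty cohort and manifest", {
  p <- syntheticParams(n_patients = 0)
  co <- generateCohort(p)
  expect_length(co$lesions, 0)
  expect_equal(nrow(co$manifest), 0)
})

test_that("a degenerate single-lesion mixture forces one lesion per patient", {
  p <- syntheticParams(n_patients = 10, lesion_count_mixture = c(1, 0, 0),
                       diameter_range_cm = c(0.9, 1.2), seed = 71)
  co <- generateCohort(p)
  expect_length(co$lesions, 10)
  expect_equal(nrow(co$manifest), 10)
  expect_length(unique(co$manifest$patient_id), 10)
})

test_that("invalid parameters are rejected", {
  expect_error(syntheticParams(lesion_count_mixture = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(syntheticParams(lf_prevalence = 1.2), "lf_prevalence")
  expect_error(syntheticParams(spacing_t1 = c(0, 0.5, 1)), "positive")
  expect_error(syntheticParams(survival_median_lc = -1), "medians")
  expect_error(syntheticParams(censor_rate = 2), "censor_rate")
})

test_that("the LF lesion fraction stays within binomial bounds of the prevalence", {
  p <- syntheticParams(n_patients = 60, lesion_count_mixture = c(1, 0, 0),
                       diameter_range_cm = c(0.9, 1.2), seed = 7)
  co <- generateCohort(p)
  n <- nrow(co$manifest)
  k <- sum(co$manifest$outcome == "LF")
  ## binomial 95% bounds around the configured prevalence
  bounds <- qbinom(c(0.025, 0.975), n, p$lf_prevalence)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("cohorts are byte-identical given the same seed and differ across seeds", {
  p <- syntheticParams(n_patients = 2, diameter_range_cm = c(0.9, 1.2),
                       seed = 5)
  c1 <- generateCohort(p)
  c2 <- generateCohort(p)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(imageValues(c1$lesions[[1]]@images$T1),
                   imageValues(c2$lesions[[1]]@images$T1))
  c3 <- generateCohort(syntheticParams(n_patients = 2,
                                       diameter_range_cm = c(0.9, 1.2),
                                       seed = 6))
  expect_false(identical(imageValues(c1$lesions[[1]]@images$T1),
                         imageValues(c3$lesions[[1]]@images$T1)))
})

test_that("generated masks satisfy the lesion-sample invariants", {
  p <- syntheticParams(n_patients = 4, seed = 72,
                       diameter_range_cm = c(0.9, 1.6))
  co <- generateCohort(p)
  for (ls in co$lesions) {
    expect_true(validObject(ls)) # tumour/edema inside brain, non-empty
    for (mod in c("T1", "FLAIR")) {
      mk <- ls@masks[[mod]]
      expect_false(any(mk$tumour@values & mk$edema@values))
      expect_identical(dim(mk$tumour@values), dim(ls@images[[mod]]@values))
    }
  }
})

test_that("clinical covariates respect their supports", {
  p <- syntheticParams(n_patients = 25, seed = 73,
                       diameter_range_cm = c(0.9, 1.2))
  co <- generateCohort(p)
  m <- co$manifest
  expect_true(all(m$total_dose %in% c(22.5, 25, 27.5, 30, 32.5, 35)))
  expect_true(all(m$max_diameter > 0))
  expect_true(all(m$histology %in% c("lung", "breast", "melanoma",
                                     "colorectal", "RCC", "other")))
  expect_true(all(m$location %in% c("supratentorium", "infratentorium")))
  expect_true(all(m$n_brain_mets >= 1))
  ## survival is a patient-level draw shared by a patient's lesions
  for (pd in split(m, m$patient_id))
    expect_length(unique(pd$survival_time), 1)
})

test_that("stronger texture separation widens the class gap in tumour GLDM-HGLE", {
  hgleGap <- function(sdLF) {
    p <- syntheticParams(
      n_patients = 60, lesion_count_mixture = c(1, 0, 0),
      lf_prevalence = 0.5, diameter_range_cm = c(0.9, 1.4),
      texture_effect = list(
        tumour = list(LC = list(corr_mm = 1.5, mean = 180, sd = 25),
                      LF = list(corr_mm = 3.0, mean = 230, sd = sdLF)),
        edema = list(LC = list(corr_mm = 2.0, mean = 140, sd = 25),
                     LF = list(corr_mm = 3.5, mean = 165, sd = 40))),
      seed = 99)
    co <- generateCohort(p)
    hgle <- vapply(co$lesions, function(ls) {
      res <- resampleToIsotropic(ls@images$FLAIR, ls@masks$FLAIR,
                                 target = 1.0)
      img <- normalizeWithinBrain(res$image, res$masks$brain, scale = 100)
      q <- quantizeROI(img, res$masks$tumour, 25)
      textureFeatures(textureMatrix(q, "GLDM"))[["HighGrayLevelEmphasis"]]
    }, numeric(1))
    cls <- co$manifest$outcome
    mean(hgle[cls == "LF"]) - mean(hgle[cls == "LC"])
  }
  weak <- hgleGap(sdLF = 32)
  strong <- hgleGap(sdLF = 55)
  expect_gt(strong, weak)
  expect_gt(strong, 0)
})

test_that("cohorts round-trip through NIfTI files and the manifest", {
  p <- syntheticParams(n_patients = 2, seed = 74,
                       diameter_range_cm = c(0.9, 1.2))
  co <- generateCohort(p)
  dir <- tempfile("cohort_")
  writeCohort(co, dir)
  back <- readCohort(dir)
  expect_equal(nrow(back$manifest), nrow(co$manifest))
  l0 <- co$lesions[[1]]
  l1 <- back$lesions[[1]]
  expect_equal(imageValues(l1@images$T1), imageValues(l0@images$T1),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(imageSpacing(l1@images$FLAIR), imageSpacing(l0@images$FLAIR),
               tolerance = 1e-6)
  expect_identical(maskValues(l1@masks$T1$tumour),
                   maskValues(l0@masks$T1$tumour))
  expect_equal(l1@images$T1@origin, l0@images$T1@origin, tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})
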