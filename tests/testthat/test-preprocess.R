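test_that("resampling is the identity on an already-isotropic grid", {
  set.seed(1)
  img <- VolumetricImage(array(rnorm(8 * 8 * 8), c(8, 8, 8)),
                         spacing = c(0.5, 0.5, 0.5))
  out <- resampleToIsotropic(img, list(), target = 0.5)
  expect_identical(dim(out$image@values), c(8L, 8L, 8L))
  expect_equal(out$image@values, img@values)
})

test_that("resampling grid arithmetic follows ceil(n * spacing / target)", {
  set.seed(2)
  img <- VolumetricImage(array(rnorm(400), c(10, 10, 4)),
                         spacing = c(0.5, 0.5, 5.0))
  out <- resampleToIsotropic(img, list(), target = 0.5)
  expect_identical(dim(out$image@values), c(10L, 10L, 40L))
})

test_that("trilinear interpolation preserves constant images and mask binarity", {
  img <- VolumetricImage(array(3.7, c(6, 5, 4)), spacing = c(1, 2, 3))
  msk <- RegionMask(array(rep(c(TRUE, FALSE), 60), c(6, 5, 4)),
                    spacing = c(1, 2, 3))
  out <- resampleToIsotropic(img, list(m = msk), target = 0.5)
  expect_equal(max(abs(out$image@values - 3.7)), 0)
  expect_true(is.logical(out$masks$m@values))
})

test_that("re-resampling to the same target is idempotent on the grid", {
  set.seed(3)
  img <- VolumetricImage(array(rnorm(5 * 7 * 3), c(5, 7, 3)),
                         spacing = c(0.7, 1.1, 2.3))
  r1 <- resampleToIsotropic(img, list(), target = 0.5)
  r2 <- resampleToIsotropic(r1$image, list(), target = 0.5)
  expect_identical(dim(r2$image@values), dim(r1$image@values))
})

test_that("brain normalization gives zero mean, unit population variance", {
  b <- RegionMask(array(TRUE, c(3, 1, 1)))
  img <- VolumetricImage(array(c(1, 2, 3), c(3, 1, 1)))
  out <- normalizeWithinBrain(img, b, scale = 1)
  expect_equal(as.numeric(out@values), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)

  set.seed(4)
  img2 <- VolumetricImage(array(rnorm(1000, 50, 7), c(10, 10, 10)))
  brain <- RegionMask(array(runif(1000) < 0.6, c(10, 10, 10)),
                      kind = "brain")
  norm <- normalizeWithinBrain(img2, brain, scale = 1)
  v <- norm@values[brain@values]
  expect_lt(abs(mean(v)), 1e-10)
  expect_lt(abs(mean((v - mean(v))^2) - 1), 1e-10)
})

test_that("normalization rejects a constant brain region", {
  b <- RegionMask(array(TRUE, c(2, 2, 2)))
  img <- constImage(c(2, 2, 2), value = 5)
  expect_error(normalizeWithinBrain(img, b), "zero.*variance")
})

test_that("margin of a single voxel matches a brute-force distance scan", {
  d <- c(41, 41, 41)
  reg <- array(FALSE, d); reg[21, 21, 21] <- TRUE
  brain <- array(TRUE, d)
  sp <- 0.5
  m <- buildMarginMask(RegionMask(reg, spacing = rep(sp, 3)),
                       RegionMask(brain, spacing = rep(sp, 3), kind = "brain"),
                       distance = 5)
  idx <- arrayInd(seq_len(prod(d)), d)
  dist <- sqrt(colSums((t(idx) - c(21, 21, 21))^2)) * sp
  expected <- dist <= 5 & dist > 0
  expect_identical(as.vector(m@values), as.vector(expected))
  expect_equal(m@kind, "tumour-margin")
})

test_that("margins clip to the brain and stay disjoint from the region", {
  d <- c(20, 20, 20)
  brain <- array(FALSE, d); brain[1:10, , ] <- TRUE
  reg <- array(FALSE, d); reg[8:10, 9:11, 9:11] <- TRUE # touches boundary
  m <- buildMarginMask(RegionMask(reg), RegionMask(brain, kind = "brain"),
                       distance = 3)
  expect_false(any(m@values & !brain))
  expect_false(any(m@values & reg))
  expect_true(any(m@values))
})

test_that("a margin smaller than the voxel pitch is empty", {
  d <- c(9, 9, 9)
  reg <- array(FALSE, d); reg[5, 5, 5] <- TRUE
  m <- buildMarginMask(RegionMask(reg), RegionMask(array(TRUE, d),
                                                   kind = "brain"),
                       distance = 0.4)
  expect_equal(sum(m@values), 0)
})

test_that("margin construction requires an isotropic grid", {
  d <- c(5, 5, 5)
  reg <- RegionMask(array(TRUE, d), spacing = c(0.5, 0.5, 5))
  expect_error(buildMarginMask(reg, reg, 5), "isotropic")
})

test_that("quantization maps intensities by zero-anchored fixed bins", {
  img <- VolumetricImage(array(c(0, 24.9, 25, 60, 0, 0, 0, 0), c(2, 2, 2)))
  msk <- RegionMask(array(c(rep(TRUE, 4), rep(FALSE, 4)), c(2, 2, 2)))
  q <- quantizeROI(img, msk, 25)
  expect_identical(sort(q@levels[q@levels > 0]), c(1L, 1L, 2L, 3L))
  expect_identical(q@nLevels, 3L)

  neg <- VolumetricImage(array(c(-30, -1, 1, rep(0, 5)), c(2, 2, 2)))
  mneg <- RegionMask(array(c(rep(TRUE, 3), rep(FALSE, 5)), c(2, 2, 2)))
  qn <- quantizeROI(neg, mneg, 25)
  expect_identical(as.vector(qn@levels[mneg@values]), c(1L, 2L, 3L))
})

test_that("a constant ROI quantizes to a single level", {
  img <- constImage(c(3, 3, 3), value = 42)
  msk <- RegionMask(array(TRUE, c(3, 3, 3)))
  q <- quantizeROI(img, msk, 25)
  expect_identical(q@nLevels, 1L)
  expect_true(all(q@levels == 1L))
})

test_that("quantization is invariant to shifts by multiples of the bin width", {
  set.seed(5)
  vals <- array(rnorm(27, 50, 40), c(3, 3, 3))
  msk <- RegionMask(array(runif(27) < 0.8, c(3, 3, 3)))
  q1 <- quantizeROI(VolumetricImage(vals), msk, 25)
  q2 <- quantizeROI(VolumetricImage(vals + 7 * 25), msk, 25)
  q3 <- quantizeROI(VolumetricImage(vals - 3 * 25), msk, 25)
  expect_identical(q1@levels, q2@levels)
  expect_identical(q1@levels, q3@levels)
})
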