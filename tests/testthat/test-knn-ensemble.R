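mkTable <- function(mat, y, pid = NULL) {
  n <- nrow(mat)
  FeatureTable(mat, data.frame(
    patient_id = pid %||% as.character(seq_len(n)),
    lesion_id = sprintf("L%03d", seq_len(n)),
    outcome = y, stringsAsFactors = FALSE))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a 1-NN model predicts a training point as its own label", {
  set.seed(51)
  mat <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- rep(c("LC", "LF"), 5)
  tab <- mkTable(mat, y)
  ens <- fitKnnEnsemble(tab, c("f1", "f2"), list(1:10), k = 1)
  pr <- predictEnsemble(ens, tab)
  expect_identical(pr$label, y)
})

test_that("identical subsets give identical models and all-or-nothing votes", {
  set.seed(52)
  mat <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- rep(c("LC", "LF"), 10)
  tab <- mkTable(mat, y)
  ens <- fitKnnEnsemble(tab, c("f1", "f2"), rep(list(1:20), 7), k = 5)
  pr <- predictEnsemble(ens, tab)
  expect_true(all(pr$vote_fraction %in% c(0, 1)))
})

test_that("vote fractions count model majorities (3-model example)", {
  ## three single-point models around the query: two vote LF, one LC
  mat <- matrix(c(0, 0, 0), 3, 1, dimnames = list(NULL, "f"))
  tab <- mkTable(mat, c("LF", "LC", "LF"))
  ens <- fitKnnEnsemble(tab, "f", list(1L, 2L, 3L), k = 1)
  pr <- predictEnsemble(ens, matrix(0, 1, 1, dimnames = list(NULL, "f")))
  expect_equal(pr$vote_fraction, 2 / 3)
  expect_equal(pr$label, "LF")
})

test_that("ensemble size follows the subset count and k too large errors", {
  set.seed(53)
  tab <- syntheticFeatureTable(30, seed = 3)
  cfg <- selectionConfig(n_subsets = 21, seed = 2)
  subs <- makeBalancedSubsets(tab, cfg)
  ens <- fitKnnEnsemble(tab, "planted|f1", subs, k = 5)
  expect_length(ens@models, 21)
  expect_error(fitKnnEnsemble(tab, "planted|f1", list(1:3), k = 5),
               "k larger")
})

test_that("with odd models and odd k no prediction is ever tied", {
  set.seed(54)
  tab <- syntheticFeatureTable(40, n_noise = 3, separation = 0.5, seed = 5)
  cfg <- selectionConfig(n_subsets = 11, seed = 8)
  subs <- makeBalancedSubsets(tab, cfg)
  ens <- fitKnnEnsemble(tab, featureIds(tab)[1:2], subs, k = 5)
  query <- matrix(rnorm(400), 200, 2,
                  dimnames = list(NULL, featureIds(tab)[1:2]))
  pr <- predictEnsemble(ens, query)
  expect_true(all(abs(pr$vote_fraction - 0.5) > 1e-12))
})

test_that("predictions are invariant to feature order and affine rescaling", {
  set.seed(55)
  tab <- syntheticFeatureTable(40, n_noise = 2, seed = 6)
  cfg <- selectionConfig(n_subsets = 5, seed = 4)
  subs <- makeBalancedSubsets(tab, cfg)
  fids <- c("planted|f1", "planted|f2", "noise|f001")
  ens <- fitKnnEnsemble(tab, fids, subs, k = 5)
  pr1 <- predictEnsemble(ens, tab)

  ## rescale one feature everywhere by an affine map
  mat2 <- featureMatrix(tab)
  mat2[, "noise|f001"] <- 10 * mat2[, "noise|f001"] - 40
  tab2 <- FeatureTable(mat2, lesionInfo(tab))
  ens2 <- fitKnnEnsemble(tab2, fids, subs, k = 5)
  pr2 <- predictEnsemble(ens2, tab2)
  expect_equal(pr1$vote_fraction, pr2$vote_fraction)

  ## feature column order in the query does not matter
  shuffled <- featureMatrix(tab)[, rev(colnames(featureMatrix(tab)))]
  pr3 <- predictEnsemble(ens, shuffled)
  expect_equal(pr1$vote_fraction, pr3$vote_fraction)
})

test_that("rank-based AUC handles separation and midrank ties", {
  expect_equal(rocAUC(c(0.2, 0.4, 0.6, 0.8), c("LC", "LC", "LF", "LF")), 1)
  expect_equal(rocAUC(c(0.4, 0.4), c("LC", "LF")), 0.5)
  expect_equal(rocAUC(c(0.8, 0.2), c("LF", "LC")), 1)
  expect_error(rocAUC(c(1, 2), c("LC", "LC")), "both classes")
})

test_that("classification metrics match the worked confusion matrix", {
  ## 13 LF with 11 correct, 17 LC with 15 correct
  truth <- c(rep("LF", 13), rep("LC", 17))
  pred <- c(rep("LF", 11), rep("LC", 2), rep("LC", 15), rep("LF", 2))
  m <- classificationMetrics(pred, truth)
  expect_equal(m$sensitivity, 100 * 11 / 13, tolerance = 1e-12)
  expect_equal(m$specificity, 100 * 15 / 17, tolerance = 1e-12)
  expect_equal(m$accuracy, 100 * 26 / 30, tolerance = 1e-12)
  expect_equal(unname(m$confusion), c(11, 15, 2, 2))

  all_right <- classificationMetrics(truth, truth)
  expect_equal(all_right$accuracy, 100)
  all_lc <- classificationMetrics(rep("LC", 30), truth)
  expect_equal(all_lc$sensitivity, 0)
})

test_that("ensembles serialize to JSON and restore identically", {
  set.seed(56)
  tab <- syntheticFeatureTable(20, n_noise = 2, seed = 7)
  cfg <- selectionConfig(n_subsets = 3, seed = 3)
  subs <- makeBalancedSubsets(tab, cfg)
  ens <- fitKnnEnsemble(tab, c("planted|f1", "noise|f001"), subs, k = 3)
  path <- tempfile(fileext = ".json")
  writeKnnEnsemble(ens, path)
  back <- readKnnEnsemble(path)
  pr1 <- predictEnsemble(ens, tab)
  pr2 <- predictEnsemble(back, tab)
  expect_equal(pr1$vote_fraction, pr2$vote_fraction)
  unlink(path)
})
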