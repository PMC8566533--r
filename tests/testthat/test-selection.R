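test_that("univariate AUC matches exhaustive pair counting and is direction-corrected", {
  ## perfectly ordered
  expect_equal(univariateAUC(1:10, c(rep("LC", 5), rep("LF", 5))), 1.0)
  ## anti-ordered: corrected back to 1
  expect_equal(univariateAUC(10:1, c(rep("LC", 5), rep("LF", 5))), 1.0)
  ## alternating classes over 1..10: frozen from the exhaustive
  ## Mann-Whitney count (15 of 25 discordant pairs -> 0.6)
  y <- rep(c("LC", "LF"), 5)
  expect_equal(univariateAUC(1:10, y), bfAUC(1:10, as.integer(y == "LF")))
  expect_equal(univariateAUC(1:10, y), 0.6)
  ## random vectors agree with the oracle after direction correction
  set.seed(41)
  for (i in 1:10) {
    x <- sample(1:8, 20, replace = TRUE) # ties included
    yy <- sample(0:1, 20, replace = TRUE)
    if (length(unique(yy)) < 2) next
    a <- bfAUC(x, yy)
    expect_equal(univariateAUC(x, yy), max(a, 1 - a), tolerance = 1e-12)
  }
  expect_error(univariateAUC(1:4, rep("LC", 4)), "both classes")
})

test_that("correlation reduction groups by connected components and keeps the best AUC", {
  set.seed(42)
  n <- 60
  f <- rnorm(n)
  g <- rnorm(n)
  y <- ifelse(f + rnorm(n, 0, 0.5) > 0, "LF", "LC")
  mat <- cbind("a|f" = f, "b|f2" = 2 * f + 1, "c|g" = g)
  tab <- FeatureTable(mat, data.frame(patient_id = as.character(1:n),
                                      lesion_id = as.character(1:n),
                                      outcome = y))
  red <- correlationReduce(tab, selectionConfig())
  expect_equal(ncol(featureMatrix(red$table)), 2)
  ## the duplicated pair collapses to one representative
  kept <- featureIds(red$table)
  expect_true("c|g" %in% kept)
  expect_equal(sum(c("a|f", "b|f2") %in% kept), 1)
  ## audit reconstructs the partition
  expect_equal(sort(unname(unlist(red$audit$components))),
               sort(colnames(mat)))
  ## no remaining pair above the threshold
  r2 <- stats::cor(featureMatrix(red$table))^2
  expect_true(all(r2[upper.tri(r2)] <= 0.8))
})

test_that("two identical features reduce to one", {
  set.seed(43)
  f <- rnorm(30)
  tab <- FeatureTable(cbind(x = f, y = f),
                      data.frame(patient_id = as.character(1:30),
                                 lesion_id = as.character(1:30),
                                 outcome = rep(c("LC", "LF"), 15)))
  red <- correlationReduce(tab, selectionConfig())
  expect_equal(ncol(featureMatrix(red$table)), 1)
})

test_that("constant features form singleton components instead of failing", {
  set.seed(44)
  tab <- FeatureTable(cbind(const = rep(1, 20), x = rnorm(20)),
                      data.frame(patient_id = as.character(1:20),
                                 lesion_id = as.character(1:20),
                                 outcome = rep(c("LC", "LF"), 10)))
  red <- correlationReduce(tab, selectionConfig())
  expect_equal(ncol(featureMatrix(red$table)), 2)
})

test_that("mRMR ranks a label copy first and matches exhaustive MID on small tables", {
  set.seed(45)
  n <- 40
  y <- rep(c("LC", "LF"), n / 2)
  ybin <- as.integer(y == "LF")
  mat <- cbind(label_copy = ybin + rnorm(n, 0, 0.01), noise = rnorm(n))
  tab <- FeatureTable(mat, data.frame(patient_id = as.character(1:n),
                                      lesion_id = as.character(1:n),
                                      outcome = y))
  expect_equal(mrmrRank(tab, pool = 2)[1], "label_copy")

  ## exhaustive MID oracle on 3 discrete features, 12 samples
  miOracle <- function(a, b) {
    tt <- table(a, b)
    p <- tt / sum(tt)
    pa <- rowSums(p); pb <- colSums(p)
    s <- 0
    for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
      if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (pa[i] * pb[j]))
    unname(s)
  }
  f1 <- c(1, 1, 2, 2, 1, 2, 1, 2, 2, 1, 2, 1)
  f2 <- c(1, 2, 1, 2, 1, 2, 2, 1, 1, 2, 2, 1)
  f3 <- c(2, 2, 2, 1, 1, 1, 2, 2, 1, 1, 2, 1)
  yy <- c("LC", "LC", "LF", "LF", "LC", "LF",
          "LC", "LF", "LF", "LC", "LF", "LC")
  tab2 <- FeatureTable(cbind(a = f1, b = f2, c = f3),
                       data.frame(patient_id = as.character(1:12),
                                  lesion_id = as.character(1:12),
                                  outcome = yy))
  got <- mrmrRank(tab2, pool = 3)
  ## greedy MID by hand
  ybin2 <- as.integer(yy == "LF")
  feats <- list(a = f1, b = f2, c = f3)
  rel <- vapply(feats, function(f) miOracle(f, ybin2), numeric(1))
  first <- names(which.max(rel))
  rest <- setdiff(names(feats), first)
  mid <- vapply(rest, function(f)
    unname(rel[f]) - miOracle(feats[[f]], feats[[first]]), numeric(1))
  expect_equal(got[1], first)
  ## the second pick attains the maximal MID score (ties allowed)
  expect_gte(mid[got[2]], max(mid) - 1e-12)
})

test_that("balanced subsets have equal class counts and no duplicates", {
  set.seed(46)
  n <- 141
  y <- c(rep("LC", 91), rep("LF", 50))
  tab <- FeatureTable(matrix(rnorm(n * 2), n, 2,
                             dimnames = list(NULL, c("f1", "f2"))),
                      data.frame(patient_id = as.character(1:n),
                                 lesion_id = as.character(1:n),
                                 outcome = y))
  cfg <- selectionConfig(n_subsets = 51, seed = 5)
  subs <- makeBalancedSubsets(tab, cfg)
  expect_length(subs, 51)
  for (s in subs) {
    expect_length(s, 100)
    expect_false(any(duplicated(s)))
    expect_equal(sum(y[s] == "LF"), 50)
    expect_equal(sum(y[s] == "LC"), 50)
    expect_true(all(which(y == "LF") %in% s)) # minority fully included
  }
  ## deterministic given the seed
  subs2 <- makeBalancedSubsets(tab, cfg)
  expect_identical(subs, subs2)
})

test_that("minority/majority roles swap with a warning when LF dominates", {
  y <- c(rep("LF", 10), rep("LC", 4))
  tab <- FeatureTable(matrix(rnorm(28), 14, 2,
                             dimnames = list(NULL, c("f1", "f2"))),
                      data.frame(patient_id = as.character(1:14),
                                 lesion_id = as.character(1:14),
                                 outcome = y))
  expect_warning(subs <- makeBalancedSubsets(tab, selectionConfig(n_subsets = 3)),
                 "undersampling")
  expect_true(all(lengths(subs) == 8))
})

test_that("cross-validated score is 1 for a label copy and near 0.5 for noise", {
  set.seed(47)
  tab <- syntheticFeatureTable(60, n_planted = 1, n_noise = 1,
                               separation = 50, seed = 8)
  cfg <- selectionConfig(n_subsets = 11, seed = 3)
  subs <- makeBalancedSubsets(tab, cfg)
  expect_equal(cvFeatureSetScore(tab, "planted|f1", subs, cfg), 1.0,
               tolerance = 1e-9)

  noise <- syntheticFeatureTable(100, n_planted = 1, n_noise = 1,
                                 separation = 0, seed = 3)
  cfgN <- selectionConfig(n_subsets = 51, seed = 3)
  subsN <- makeBalancedSubsets(noise, cfgN)
  sc <- cvFeatureSetScore(noise, "noise|f001", subsN, cfgN)
  expect_gt(sc, 0.4)
  expect_lt(sc, 0.6)
})

test_that("cross-validation folds never split a patient", {
  tab <- syntheticFeatureTable(30, seed = 9)
  cfg <- selectionConfig(n_subsets = 5, cv_folds = 5, seed = 2)
  subs <- makeBalancedSubsets(tab, cfg)
  folds <- BrainMetRadiomics:::.subsetFolds(tab, subs, cfg)
  pid <- lesionInfo(tab)$patient_id
  for (s in seq_along(subs)) {
    byPatient <- split(folds[[s]], pid[subs[[s]]])
    for (f in byPatient) expect_length(unique(f), 1)
  }
})

test_that("forward selection finds a planted separator first and stops on noise", {
  tab <- syntheticFeatureTable(50, n_planted = 1, n_noise = 20,
                               separation = 6, seed = 10)
  cfg <- selectionConfig(n_subsets = 11, max_features = 4,
                         min_improvement = 1e-3, seed = 4)
  res <- sequentialForwardSelect(tab, featureIds(tab), cfg)
  expect_equal(res$selected[1], "planted|f1")

  allnoise <- syntheticFeatureTable(50, n_planted = 1, n_noise = 15,
                                    separation = 0, seed = 12)
  resN <- sequentialForwardSelect(allnoise, featureIds(allnoise), cfg)
  expect_lte(length(resN$selected), cfg$max_features)
  expect_lt(max(resN$scores), 0.75)
})

test_that("a complementary pair is selected together when offered alone", {
  ## XOR-like construction: neither feature separates alone, the pair does
  set.seed(48)
  n <- 120
  f1 <- rnorm(n)
  f2 <- rnorm(n)
  y <- ifelse(f1 * f2 > 0, "LF", "LC")
  tab <- FeatureTable(cbind("pair|f1" = f1, "pair|f2" = f2),
                      data.frame(patient_id = as.character(1:n),
                                 lesion_id = as.character(1:n),
                                 outcome = y))
  cfg <- selectionConfig(n_subsets = 11, max_features = 2, seed = 6)
  res <- sequentialForwardSelect(tab, featureIds(tab), cfg)
  expect_setequal(res$selected, c("pair|f1", "pair|f2"))
  expect_gt(res$scores[2], 0.8)
})

test_that("the full selection pipeline is deterministic given the seed", {
  tab <- syntheticFeatureTable(40, n_noise = 15, seed = 14)
  cfg <- selectionConfig(n_subsets = 11, seed = 7)
  r1 <- selectFeatures(tab, cfg)
  r2 <- selectFeatures(tab, cfg)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$scores, r2$scores)
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  for (i in 1:5) {
    x <- rnorm(60)
    y <- sample(c("LC", "LF"), 60, replace = TRUE)
    if (length(unique(y)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(y, x, levels = c("LC", "LF"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(rocAUC(x, y), ref, tolerance = 1e-12)
    expect_equal(univariateAUC(x, y), max(ref, 1 - ref), tolerance = 1e-12)
  }
})
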