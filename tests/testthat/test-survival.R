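test_that("patients with any LF lesion are assigned to the LF cohort", {
  pid <- c("A", "A", "B", "B", "B", "C")
  out <- c("LC", "LF", "LC", "LC", "LC", "LF")
  coh <- assignPatientCohorts(pid, out)
  expect_equal(coh[["A"]], "LF")
  expect_equal(coh[["B"]], "LC")
  expect_equal(coh[["C"]], "LF")
  expect_error(assignPatientCohorts(character(0), character(0)), "no lesions")
})

test_that("the product-limit estimator matches the hand-computed example", {
  ## times {1 event, 2 censored, 3 event}: S = 2/3 at t=1, 2/3 at 2, 0 at 3
  km <- kmCurve(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(km$surv, c(2 / 3, 2 / 3, 0), tolerance = 1e-12)
  expect_equal(km$median, 3)
})

test_that("all-censored data keep the curve at one with undefined median", {
  km <- kmCurve(c(2, 4, 6), c(FALSE, FALSE, FALSE))
  expect_true(all(km$surv == 1))
  expect_true(is.na(km$median))
})

test_that("without censoring the curve is the empirical survivor function", {
  set.seed(61)
  t <- sort(rexp(40, 0.1))
  km <- kmCurve(t, rep(TRUE, 40))
  emp <- vapply(km$time, function(u) mean(t > u), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("log-rank on identical groups gives statistic 0 and p 1", {
  t <- c(1, 2, 3, 4, 5, 6)
  e <- c(1, 1, 0, 1, 1, 0)
  lr <- logrankTest(c(t, t), c(e, e), rep(c("A", "B"), each = 6))
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)
})

test_that("log-rank matches the hand-computed hypergeometric tally", {
  ## A = {1e, 2e}, B = {3e, 4e}; observed minus expected events in A:
  ## t=1: O=1, E=2/4 (2 of 4 at risk in A); t=2: O=1, E=1/3;
  ## t=3, t=4: no A patients at risk, E=0 -> U = 1/2 + 2/3 = 7/6
  ## V = sum of hypergeometric variances nA nB d (n - d) / (n^2 (n - 1))
  tA <- c(1, 2); tB <- c(3, 4)
  U <- (1 - 2 / 4) + (1 - 1 / 3)
  V1 <- (2 / 4) * (2 / 4) * 1 * (3 / 3) # t=1: n=4, nA=nB=2, d=1
  V2 <- (1 / 3) * (2 / 3) * 1 * (2 / 2) # t=2: n=3, nA=1, nB=2
  chi <- U^2 / (V1 + V2)
  lr <- logrankTest(c(tA, tB), rep(1, 4), rep(c("A", "B"), each = 2))
  expect_equal(lr$chi_square, chi, tolerance = 1e-10)
  ## invariant under swapping group labels
  lr2 <- logrankTest(c(tA, tB), rep(1, 4), rep(c("B", "A"), each = 2))
  expect_equal(lr$chi_square, lr2$chi_square, tolerance = 1e-12)
})

test_that("exponential arms at the study medians separate at n = 40 per arm", {
  set.seed(11)
  tLC <- rexp(40, log(2) / 26.2)
  tLF <- rexp(40, log(2) / 13.5)
  lr <- logrankTest(c(tLC, tLF), rep(1, 80), rep(c("LC", "LF"), each = 40))
  expect_lt(lr$p_value, 0.05)
})

test_that("predicted and labelled cohorts give concordant significance at high accuracy", {
  set.seed(62)
  concordant <- 0
  for (rep in 1:10) {
    n <- 120
    pid <- sprintf("P%02d", 1:n)
    truth <- ifelse(runif(n) < 0.4, "LF", "LC")
    ## ~90% accurate prediction
    pred <- ifelse(runif(n) < 0.9, truth,
                   ifelse(truth == "LF", "LC", "LF"))
    time <- ifelse(truth == "LF", rexp(n, log(2) / 13.5),
                   rexp(n, log(2) / 26.2))
    df <- data.frame(patient_id = pid, outcome = truth, predicted = pred,
                     survival_time = time, survival_event = TRUE)
    sc <- survivalComparison(df)
    sigT <- sc$label$logrank$p_value < 0.05
    sigP <- sc$predicted$logrank$p_value < 0.05
    if (sigT == sigP) concordant <- concordant + 1
  }
  expect_gte(concordant, 8)
})

test_that("synthetic survival draws reproduce the configured medians", {
  p <- syntheticParams(censor_rate = 0)
  set.seed(63)
  tLC <- replicate(10000, synthSurvival("LC", p)$time)
  tLF <- replicate(10000, synthSurvival("LF", p)$time)
  expect_equal(median(tLC), 26.2, tolerance = 0.05)
  expect_equal(median(tLF), 13.5, tolerance = 0.05)
  ## no censoring: every event observed
  ev <- replicate(50, synthSurvival("LC", p)$event)
  expect_true(all(ev))
})

test_that("censoring applies at the configured rate", {
  p <- syntheticParams(censor_rate = 0.3)
  set.seed(64)
  ev <- replicate(4000, synthSurvival("LC", p)$event)
  expect_equal(mean(!ev), 0.3, tolerance = 0.03)
})
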