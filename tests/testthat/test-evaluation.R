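test_that("stratified folds balance classes within one subject", {
  manifest <- data.frame(
    subject_id = sprintf("s%02d", 1:73),
    label = c(rep("MDD", 29), rep("HC", 44)))
  folds <- stratifiedFolds(manifest, k = 10, seed = 3)
  testSets <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(testSets)), sort(manifest$subject_id))
  expect_equal(sum(duplicated(unlist(testSets))), 0L)
  for (f in folds) {
    nMdd <- sum(f$test %in% manifest$subject_id[1:29])
    nHc <- sum(f$test %in% manifest$subject_id[30:73])
    expect_true(nMdd %in% 2:3)
    expect_true(nHc %in% 4:5)
    expect_equal(sort(c(f$train, f$test)), sort(manifest$subject_id))
  }
  expect_identical(folds, stratifiedFolds(manifest, k = 10, seed = 3))
  expect_error(stratifiedFolds(manifest[1:12, ], k = 10), "smaller than k")
})

test_that("confusion-based metrics follow the printed formulas", {
  truth <- c("MDD", "MDD", "MDD", "HC", "HC", "HC", "HC")
  pred  <- c("MDD", "MDD", "HC", "HC", "HC", "HC", "MDD")
  m <- classificationMetrics(truth, pred)
  expect_equal(m$ACC, 5 / 7)
  expect_equal(m$SEN, 2 / 3)
  expect_equal(m$SPE, 3 / 4)
  expect_equal(c(m$TP, m$TN, m$FP, m$FN), c(2, 3, 1, 1))
})

test_that("rank-based AUC handles separation, ties and transforms", {
  truth <- c(rep("MDD", 3), rep("HC", 4))
  perfect <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1, 0.05)
  expect_equal(classificationMetrics(truth, truth, perfect)$AUC, 1.0)
  expect_equal(classificationMetrics(truth, truth, rep(0.5, 7))$AUC, 0.5)
  set.seed(1)
  sc <- runif(7)
  a1 <- classificationMetrics(truth, truth, sc)$AUC
  a2 <- classificationMetrics(truth, truth, exp(3 * sc))$AUC
  expect_equal(a1, a2)
  expect_warning(classificationMetrics(rep("HC", 4), rep("HC", 4)),
                 "SEN undefined")
})

test_that("McNemar branches give the stated statistics and p-values", {
  mkPreds <- function(b, c, nBoth = 5) {
    # truth all "MDD"; A and B disagree on b + c subjects
    n <- b + c + nBoth
    truth <- rep("MDD", n)
    predA <- rep("MDD", n)
    predB <- rep("MDD", n)
    if (b > 0) predB[seq_len(b)] <- "HC"            # A right, B wrong
    if (c > 0) predA[b + seq_len(c)] <- "HC"        # A wrong, B right
    list(truth = truth, a = predA, b = predB)
  }
  sym <- mkPreds(6, 6)
  res <- mcnemarTest(sym$truth, sym$a, sym$b)
  expect_equal(res$p.value, 1)

  ex <- mkPreds(10, 2)
  res2 <- mcnemarTest(ex$truth, ex$a, ex$b)
  expect_equal(res2$method, "exact binomial")
  expect_equal(res2$p.value, 2 * pbinom(2, 12, 0.5), tolerance = 1e-10)
  expect_equal(round(res2$p.value, 4), 0.0386)

  cc <- mkPreds(40, 20)
  res3 <- mcnemarTest(cc$truth, cc$a, cc$b)
  expect_equal(res3$statistic, 19^2 / 60, tolerance = 1e-10)
  expect_equal(round(res3$statistic, 4), 6.0167)

  none <- mkPreds(0, 0)
  res4 <- mcnemarTest(none$truth, none$a, none$b)
  expect_equal(res4$p.value, 1)
  expect_equal(res4$statistic, 0)

  # exact and continuity-corrected branches agree near the cutover
  mid <- mkPreds(19, 11)
  pExact <- mcnemarTest(mid$truth, mid$a, mid$b, exactThreshold = 100)$p.value
  pCc <- mcnemarTest(mid$truth, mid$a, mid$b, exactThreshold = 1)$p.value
  expect_lt(abs(pExact - pCc), 0.02)
})

test_that("Pearson chi-square reproduces the demographic statistics", {
  gender <- rbind(c(21, 27), c(8, 17))
  res <- pearsonChiSquare(gender)
  expect_equal(res$statistic, 0.948, tolerance = 1e-3)
  expect_equal(res$dof, 1)

  education <- rbind(c(7, 2), c(21, 35), c(1, 7))
  res2 <- pearsonChiSquare(education)
  expect_equal(res2$statistic, 8.035, tolerance = 1e-3)
  expect_equal(res2$dof, 2)

  indep <- outer(c(10, 20), c(3, 7))
  expect_lt(pearsonChiSquare(indep)$statistic, 1e-10)
  expect_error(pearsonChiSquare(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("summary-statistic t tests reproduce the demographic rows", {
  expect_equal(twoSampleT(5, 1, 10, 5, 2, 12)$statistic, 0)
  age <- twoSampleT(43.79, 13.06, 29, 39.68, 11.91, 44, "pooled")
  expect_equal(age$statistic, 1.389, tolerance = 0.01)
  hdrs <- twoSampleT(14.48, 4.82, 29, 1.98, 2.11, 44, "welch")
  expect_equal(hdrs$statistic, 13.166, tolerance = 0.02)
})

test_that("confidence-interval arithmetic scales as z * sd / sqrt(n)", {
  ci <- sensitivityCi(0.566, 0.300, 10, 1.96)
  expect_equal(ci$marginalError, 0.186, tolerance = 5e-4)
  expect_equal(ci$ci, c(0.380, 0.752), tolerance = 5e-4)

  degenerate <- sensitivityCi(0.7, 0, 10)
  expect_equal(degenerate$ci, c(0.7, 0.7))

  me1 <- sensitivityCi(0.5, 0.2, 10)$marginalError
  me4 <- sensitivityCi(0.5, 0.2, 40)$marginalError
  expect_equal(me1 / me4, 2)
})

test_that("diagnostic power increases with cases and tolerance", {
  p1 <- diagnosticPower(0.566, 0.186, 29)
  p2 <- diagnosticPower(0.566, 0.186, 100)
  p3 <- diagnosticPower(0.566, 0.10, 29)
  expect_gt(p2, p1)
  expect_lt(p3, p1)
  expect_true(p1 > 0 && p1 < 1)
})
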