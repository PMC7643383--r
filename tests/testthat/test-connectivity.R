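test_that("zero penalty reduces to per-subject ordinary least squares", {
  fix <- simulateRegressionFixture(T = 80, R = 5, sparsity = 2,
                                   noiseSd = 0.1, nSubjects = 1, seed = 3)
  ec <- groupSparseEC(fix$series,
                      solverConfig(alpha = 0, tol = 1e-12,
                                   maxIter = 20000, standardizeInputs = FALSE))
  x <- seriesData(fix$series[[1]])
  ols <- qr.coef(qr(x[, -1]), x[, 1])
  expect_lt(max(abs(ecMatrices(ec)[[1]][-1, 1] - ols)), 1e-6)
})

test_that("alphaMax matches the subgradient condition at zero", {
  # zero response -> gradient at zero vanishes
  set.seed(4)
  x <- matrix(rnorm(40), 20, 2)
  x[, 1] <- 0
  ser <- list(RoiTimeSeries(x, 2))
  expect_equal(alphaMax(ser, 1, standardizeInputs = FALSE), 0)

  # single unit-norm predictor equal to the response -> inner product 1
  v <- rnorm(30); v <- v / sqrt(sum(v^2))
  ser2 <- list(RoiTimeSeries(cbind(v, v), 2))
  expect_equal(alphaMax(ser2, 1, standardizeInputs = FALSE), 1,
               tolerance = 1e-12)
})

test_that("penalties above alphaMax null the solution, below keep rows", {
  co <- simulateCohort(nMdd = 1, nHc = 1, R = 4, T = 50, seed = 5)
  am <- alphaMax(co$series, 2)
  ecHi <- groupSparseEC(co$series, solverConfig(alpha = 1.001 * am))
  col2 <- sapply(ecMatrices(ecHi), function(m) m[, 2])
  expect_true(all(col2 == 0))
  ecLo <- groupSparseEC(co$series, solverConfig(alpha = 0.5 * am))
  nnzRows <- sum(rowSums(abs(sapply(ecMatrices(ecLo),
                                    function(m) m[-2, 2]))) > 0)
  expect_gte(nnzRows, 1L)
})

test_that("solver matches a brute-force minimizer on tiny instances", {
  set.seed(42)
  for (inst in 1:3) {
    N <- sample(1:3, 1); R <- sample(3:5, 1); T <- sample(15:30, 1)
    ser <- lapply(seq_len(N), function(n)
      RoiTimeSeries(matrix(rnorm(T * R), T, R), 2, paste0("s", n)))
    alpha <- 0.3 * alphaMax(ser, 1)
    ec <- groupSparseEC(ser, solverConfig(alpha = alpha, tol = 1e-12,
                                          maxIter = 20000))
    prob <- standardizedProblem(ser, 1)
    objFista <- groupObjectiveOracle(ecDestinationVector(ec, 1),
                                     prob$Xs, prob$ys, alpha)
    best <- Inf
    for (st in 1:5) {
      w0 <- rnorm((R - 1) * N, 0, 0.3)
      o <- optim(w0, groupObjectiveOracle, Xs = prob$Xs, ys = prob$ys,
                 alpha = alpha, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
      ## simplex polish: BFGS can stall at the penalty's kinks
      o2 <- optim(o$par, groupObjectiveOracle, Xs = prob$Xs,
                  ys = prob$ys, alpha = alpha, method = "Nelder-Mead",
                  control = list(maxit = 20000, reltol = 1e-15))
      best <- min(best, o$value, o2$value)
    }
    expect_lt(abs(objFista - best), 1e-4)
  }
})

test_that("solver objective is non-increasing across iterations", {
  co <- simulateCohort(nMdd = 2, nHc = 2, R = 5, T = 60, seed = 8)
  ec <- groupSparseEC(co$series, solverConfig(alpha = "auto"))
  for (traj in attr(ec, "trajectories")) {
    if (length(traj) > 1) expect_true(all(diff(traj) <= 1e-10))
  }
})

test_that("connection rows share their support across subjects", {
  fix <- simulateRegressionFixture(T = 100, R = 6, sparsity = 2,
                                   noiseSd = 0.2, nSubjects = 3, seed = 9)
  am <- alphaMax(fix$series, 1)
  ec <- groupSparseEC(fix$series, solverConfig(alpha = 0.2 * am))
  W <- sapply(ecMatrices(ec), function(m) m[-1, 1])   # (R-1) x N
  for (j in seq_len(nrow(W))) {
    nz <- abs(W[j, ]) > 1e-10
    expect_true(all(nz) || all(!nz))
  }
})

test_that("support size is monotone non-increasing in alpha", {
  co <- simulateCohort(nMdd = 2, nHc = 2, R = 5, T = 60, seed = 10)
  am <- max(sapply(1:5, function(r) alphaMax(co$series, r)))
  sizes <- sapply(c(0.05, 0.15, 0.4, 0.8, 1.05), function(mult)
    sum(supportMask(groupSparseEC(co$series,
                                  solverConfig(alpha = mult * am)))))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[length(sizes)], 0L)
})

test_that("noiseless shared-support fixture is recovered exactly", {
  fix <- simulateRegressionFixture(T = 120, R = 6, sparsity = 2,
                                   noiseSd = 0, nSubjects = 2, seed = 11)
  ec <- groupSparseEC(fix$series,
                      solverConfig(alpha = 1e-4, tol = 1e-14,
                                   maxIter = 50000,
                                   standardizeInputs = FALSE))
  W <- sapply(ecMatrices(ec), function(m) m[-1, 1])
  expect_lt(max(abs(W - fix$coefficients)), 1e-3)
  estSupport <- rowSums(abs(W)) > 1e-6
  trueSupport <- rowSums(abs(fix$coefficients)) > 0
  expect_identical(estSupport, trueSupport)
})

test_that("Pearson FC matches the product-moment formula", {
  set.seed(12)
  x <- matrix(rnorm(200), 50, 4)
  x[, 2] <- -x[, 1]
  fc <- fcMatrix(pearsonFC(RoiTimeSeries(x, 2)))
  expect_true(all(diag(fc) == 1))
  expect_equal(fc[1, 2], -1, tolerance = 1e-12)

  # hand-computed product-moment correlation for (1,2,3,4) vs (1,2,3,5)
  y <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 5), rnorm(4))
  fc2 <- fcMatrix(pearsonFC(RoiTimeSeries(y, 2)))
  expect_equal(fc2[1, 2], 0.9827, tolerance = 1e-4)

  # invariance under positive affine rescaling of a column
  x2 <- x; x2[, 3] <- 4.2 * x2[, 3] + 7
  fc3 <- fcMatrix(pearsonFC(RoiTimeSeries(x2, 2)))
  expect_equal(fc3, fc, tolerance = 1e-12)

  expect_error(pearsonFC(RoiTimeSeries(cbind(rep(1, 10), rnorm(10)), 2)),
               "constant")
})

test_that("Granger causality detects lagged influence, not independence", {
  set.seed(13)
  ts <- RoiTimeSeries(matrix(rnorm(4000), 2000, 2), 2)
  g <- grangerEC(ts, order = 1)
  expect_true(all(diag(g) == 0))
  expect_lt(max(g), 0.01)
  expect_true(all(g >= 0))

  A <- matrix(0, 2, 2); A[1, 2] <- 0.9
  lagged <- simulateVar1(A, T = 500, noiseSd = 0.3, seed = 1)
  g2 <- grangerEC(lagged, order = 1)
  expect_gt(g2[1, 2], g2[2, 1])

  short <- RoiTimeSeries(matrix(rnorm(8), 4, 2), 2)
  expect_error(grangerEC(short, 1), "time points")
})

test_that("vectorization layouts and lengths match the parcellation", {
  expect_length(vectorizeConnectivity(diag(0, 114), "fc"), 6441L)
  vec <- vectorizeConnectivity(matrix(rnorm(114^2), 114, 114) *
                                 (1 - diag(114)), "ec")
  expect_length(vec, 12996L)
  expect_equal(sum(vec == 0), 114L)

  m <- matrix(0, 3, 3); m[2, 1] <- 0.7
  expect_equal(vectorizeConnectivity(m, "ec")[2], 0.7)

  fm <- matrix(0, 3, 3); fm[1, 2] <- 1; fm[1, 3] <- 2; fm[2, 3] <- 3
  expect_equal(vectorizeConnectivity(fm + t(fm) + diag(3), "fc"),
               c(1, 2, 3))

  expect_error(vectorizeConnectivity(matrix(0, 2, 3), "ec"), "square")
})
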