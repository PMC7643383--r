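# Shared separable cohort: large class effect, trained once and reused.
sepCohort <- local({
  co <- simulateCohort(effectSize = 5, seed = 0)
  fc <- t(sapply(co$series, function(ts)
    vectorizeConnectivity(pearsonFC(ts), "fc")))
  labels <- as.character(co$manifest$label)
  sel <- fitLassoSelector(fc, labels, lambda = "auto", seed = 1)
  f <- applySelector(sel, fc)
  g <- buildAdjacency(f, co$manifest[, c("age", "gender")])
  list(features = f, labels = labels, op = spectralOperator(g),
       manifest = co$manifest)
})

test_that("initialization is seed-reproducible with the stated shapes", {
  m1 <- initGcn(5, hiddenDims = 16, K = 3, seed = 9)
  m2 <- initGcn(5, hiddenDims = 16, K = 3, seed = 9)
  expect_identical(m1@layers, m2@layers)
  expect_equal(dim(m1@layers[[1]]$theta), c(4L, 5L, 16L))
  expect_equal(dim(m1@layers[[2]]$theta), c(4L, 16L, 2L))

  m3 <- initGcn(5, hiddenDims = integer(), K = 2, seed = 1)
  expect_length(m3@layers, 1L)
  expect_equal(dim(m3@layers[[1]]$theta), c(3L, 5L, 2L))
  expect_error(initGcn(5, K = -1), "K")
})

test_that("K = 0 single-layer model is plain softmax regression", {
  fx <- makeOperator(n = 5, seed = 31)
  m <- initGcn(3, hiddenDims = integer(), K = 0, seed = 2)
  f <- matrix(rnorm(15), 5, 3)
  p <- gcnForward(m, fx$op, f)$probabilities
  theta0 <- matrix(m@layers[[1]]$theta[1, , ], 3, 2)
  manual <- exp(f %*% theta0 + rep(m@layers[[1]]$bias, each = 5))
  manual <- manual / rowSums(manual)
  expect_equal(p, manual, tolerance = 1e-12)
})

test_that("an edgeless graph gives no cross-subject mixing", {
  w <- matrix(0, 4, 4)
  op <- spectralOperator(w)
  m <- initGcn(2, hiddenDims = 3, K = 3, seed = 5)
  f <- matrix(rnorm(8), 4, 2)
  p1 <- gcnForward(m, op, f)$probabilities
  f2 <- f; f2[2, ] <- f2[2, ] + 5
  p2 <- gcnForward(m, op, f2)$probabilities
  expect_equal(p1[-2, ], p2[-2, ], tolerance = 1e-12)
  expect_gt(max(abs(p1[2, ] - p2[2, ])), 1e-6)
})

test_that("automorphic vertices with equal features get equal outputs", {
  # 4-cycle: vertices 1 and 3 are automorphic, as are 2 and 4
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 3] <- w[3, 4] <- w[4, 1] <- 1
  w <- w + t(w)
  op <- spectralOperator(w)
  f <- rbind(c(1, 2), c(3, 4), c(1, 2), c(3, 4))
  m <- initGcn(2, hiddenDims = 3, K = 3, seed = 6)
  p <- gcnForward(m, op, f)$probabilities
  expect_equal(p[1, ], p[3, ], tolerance = 1e-10)
  expect_equal(p[2, ], p[4, ], tolerance = 1e-10)
})

test_that("Chebyshev recurrence equals explicit spectral filtering", {
  fx <- makeOperator(n = 8, seed = 32)
  e <- eigen(scaledLaplacian(fx$op), symmetric = TRUE)
  K <- 3
  set.seed(33)
  theta <- rnorm(K + 1)
  f <- matrix(rnorm(16), 8, 2)
  basis <- ecgcn:::chebyshevBasis(fx$op, K)
  viaRecurrence <- Reduce(`+`, lapply(0:K, function(k)
    theta[k + 1] * basis[[k + 1]] %*% f))
  tk <- matrix(0, 8, K + 1)
  tk[, 1] <- 1
  tk[, 2] <- e$values
  for (k in 3:(K + 1)) tk[, k] <- 2 * e$values * tk[, k - 1] - tk[, k - 2]
  g <- rowSums(sweep(tk, 2, theta, "*"))
  viaEigen <- e$vectors %*% diag(g) %*% t(e$vectors) %*% f
  expect_lt(max(abs(viaRecurrence - viaEigen)), 1e-8)
})

test_that("analytic gradients match central finite differences", {
  fx <- makeOperator(n = 6, seed = 34)
  m <- initGcn(3, hiddenDims = 4, K = 2, seed = 7)
  f <- matrix(rnorm(18), 6, 3)
  err <- gradientCheck(m, fx$op, f, altLabels(6), epsilon = 1e-5,
                       weightDecay = 5e-4)
  expect_lt(err, 1e-5)
})

test_that("K = 0 gradient equals the closed-form softmax regression one", {
  fx <- makeOperator(n = 6, seed = 35)
  m <- initGcn(3, hiddenDims = integer(), K = 0, seed = 8)
  f <- matrix(rnorm(18), 6, 3)
  labels <- altLabels(6)
  res <- ecgcn:::.gcnLossGrad(m, fx$op, f, labels, rep(TRUE, 6), 0)
  Y <- ecgcn:::.oneHot(labels, 6, 2)
  manualTheta <- crossprod(f, res$probabilities - Y) / 6
  manualBias <- colSums(res$probabilities - Y) / 6
  expect_lt(max(abs(matrix(res$grads[[1]]$theta[1, , ], 3, 2) -
                      manualTheta)), 1e-8)
  expect_lt(max(abs(res$grads[[1]]$bias - manualBias)), 1e-8)
})

test_that("zero features zero the weight gradients but not the bias", {
  fx <- makeOperator(n = 5, seed = 36)
  m <- initGcn(3, hiddenDims = integer(), K = 2, seed = 9)
  f <- matrix(0, 5, 3)
  res <- ecgcn:::.gcnLossGrad(m, fx$op, f, altLabels(5), rep(TRUE, 5), 0)
  expect_equal(max(abs(res$grads[[1]]$theta)), 0)
  expect_gt(max(abs(res$grads[[1]]$bias)), 1e-6)
})

test_that("a separable cohort is fitted perfectly by epoch 200", {
  m <- initGcn(ncol(sepCohort$features), hiddenDims = 16, K = 3, seed = 0)
  fit <- trainGcn(m, sepCohort$op, sepCohort$features, sepCohort$labels,
                  rep(TRUE, nrow(sepCohort$features)),
                  trainConfig(seed = 0))
  pred <- gcnPredict(fit$model, sepCohort$op, sepCohort$features)
  expect_equal(mean(as.character(pred$labels) == sepCohort$labels), 1.0)
  # loss decreases over the first 10 epochs
  expect_true(all(diff(fit$lossTrajectory[1:10]) < 0))
})

test_that("held-out subjects of a separable cohort are classified", {
  n <- nrow(sepCohort$features)
  test <- seq(1, n, by = 5)
  mask <- !(seq_len(n) %in% test)
  labs <- sepCohort$labels
  labs[!mask] <- NA
  m <- initGcn(ncol(sepCohort$features), hiddenDims = 16, K = 3, seed = 1)
  fit <- trainGcn(m, sepCohort$op, sepCohort$features, labs, mask,
                  trainConfig(seed = 1))
  pred <- gcnPredict(fit$model, sepCohort$op, sepCohort$features)
  acc <- mean(as.character(pred$labels[test]) == sepCohort$labels[test])
  expect_gt(acc, 0.9)
})

test_that("unlabeled vertices' label values are never read in training", {
  n <- nrow(sepCohort$features)
  mask <- rep(c(TRUE, TRUE, TRUE, FALSE), length.out = n)
  labsNa <- sepCohort$labels; labsNa[!mask] <- NA
  labsPoisonA <- sepCohort$labels; labsPoisonA[!mask] <- "MDD"
  labsPoisonB <- sepCohort$labels; labsPoisonB[!mask] <- "HC"
  m <- initGcn(ncol(sepCohort$features), hiddenDims = 4, K = 1, seed = 2)
  cfg <- trainConfig(epochs = 20, seed = 3)
  f1 <- trainGcn(m, sepCohort$op, sepCohort$features, labsNa, mask, cfg)
  f2 <- trainGcn(m, sepCohort$op, sepCohort$features, labsPoisonA, mask, cfg)
  f3 <- trainGcn(m, sepCohort$op, sepCohort$features, labsPoisonB, mask, cfg)
  expect_identical(f1$model@layers, f2$model@layers)
  expect_identical(f1$model@layers, f3$model@layers)
})

test_that("extreme weight decay collapses the filter weights", {
  fx <- makeOperator(n = 8, seed = 37)
  f <- matrix(rnorm(24), 8, 3)
  m <- initGcn(3, hiddenDims = 4, K = 2, seed = 10)
  init <- max(abs(ecgcn:::.paramsToVector(m@layers)))
  # step size kept below 1/weightDecay so the decay flow is stable
  fit <- trainGcn(m, fx$op, f, altLabels(8), rep(TRUE, 8),
                  trainConfig(learningRate = 5e-4, weightDecay = 1e3,
                              dropout = 0, seed = 4))
  final <- max(abs(unlist(lapply(fit$model@layers,
                                 function(l) as.numeric(l$theta)))))
  expect_lt(final, 0.1 * init)
})

test_that("training and prediction are deterministic given seeds", {
  fx <- makeOperator(n = 8, seed = 38)
  f <- matrix(rnorm(24), 8, 3)
  cfg <- trainConfig(epochs = 30, seed = 5)
  run <- function() {
    m <- initGcn(3, hiddenDims = 4, K = 2, seed = 11)
    trainGcn(m, fx$op, f, altLabels(8), rep(TRUE, 8), cfg)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$model@layers, f2$model@layers)
  p1 <- gcnPredict(f1$model, fx$op, f)
  p2 <- gcnPredict(f1$model, fx$op, f)
  expect_identical(p1, p2)
  expect_lt(max(abs(rowSums(p1$probabilities) - 1)), 1e-10)
})
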