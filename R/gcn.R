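#' Training hyperparameters for the graph convolutional network
#'
#' Defaults follow the study configuration: dropout 0.3, learning rate
#' 0.05, l2 weight decay 5e-4, 200 epochs, full-batch gradient descent.
#'
#' @param learningRate Positive step size.
#' @param dropout Dropout rate in [0, 1), applied (inverted) to the input
#'   features and hidden activations during training only.
#' @param weightDecay Non-negative l2 penalty on the filter coefficients
#'   (biases are not penalized); the loss term is (weightDecay/2) sum
#'   theta^2.
#' @param epochs Number of full-batch epochs.
#' @param seed Integer seed controlling dropout masks (and Adam state).
#' @param optimizer `"gd"` (plain gradient descent, default) or `"adam"`.
#' @return A list of class `TrainConfig`.
#' @export
trainConfig <- function(learningRate = 0.05, dropout = 0.3,
                        weightDecay = 5e-4, epochs = 200L, seed = 1L,
                        optimizer = c("gd", "adam")) {
  optimizer <- match.arg(optimizer)
  stopifnot2(learningRate > 0, "learningRate must be positive")
  stopifnot2(dropout >= 0 && dropout < 1, "dropout must lie in [0, 1)")
  stopifnot2(weightDecay >= 0, "weightDecay must be non-negative")
  structure(list(learningRate = learningRate, dropout = dropout,
                 weightDecay = weightDecay, epochs = as.integer(epochs),
                 seed = as.integer(seed), optimizer = optimizer),
            class = "TrainConfig")
}

#' Initialize a Chebyshev spectral GCN
#'
#' Filter coefficient tensors are Glorot-uniform (limit
#' sqrt(6 / (F_in (K+1) + F_out)), counting all K+1 basis terms as fan-in);
#' biases start at zero. Initialization is bit-reproducible from `seed`.
#'
#' @param fIn Input feature dimension (>= 1).
#' @param hiddenDims Integer vector of hidden widths; `integer(0)` gives a
#'   single softmax layer (logistic-regression-like model).
#' @param K Chebyshev order (K >= 0; K+1 basis terms per filter).
#' @param seed Integer seed.
#' @param nClasses Number of classes (2).
#' @return A [GcnModel-class].
#' @examples
#' m <- initGcn(fIn = 5, hiddenDims = 16, K = 3, seed = 1)
#' m
#' @export
initGcn <- function(fIn, hiddenDims = 16L, K = 3L, seed = 1L,
                    nClasses = 2L) {
  K <- as.integer(K)
  stopifnot2(K >= 0L, "K must be non-negative")
  stopifnot2(fIn >= 1L, "fIn must be at least 1")
  dims <- c(as.integer(fIn), as.integer(hiddenDims), as.integer(nClasses))
  layers <- withSeed(seed, lapply(seq_len(length(dims) - 1L), function(l) {
    fi <- dims[l]; fo <- dims[l + 1L]
    limit <- sqrt(6 / (fi * (K + 1L) + fo))
    theta <- array(stats::runif((K + 1L) * fi * fo, -limit, limit),
                   dim = c(K + 1L, fi, fo))
    list(theta = theta, bias = numeric(fo))
  }))
  new("GcnModel", layers = layers, K = K,
      hiddenDims = as.integer(hiddenDims), nClasses = as.integer(nClasses),
      trained = FALSE)
}

## F_in x F_out coefficient matrix of basis order k (1-based), robust to
## singleton dimensions.
.thetaSlice <- function(layer, k) {
  d <- dim(layer$theta)
  matrix(layer$theta[k, , ], d[2L], d[3L])
}

## One convolution layer: Z = sum_k T_k(Ls) H theta_k + bias.
.layerForward <- function(basis, H, layer) {
  K1 <- dim(layer$theta)[1L]
  TkH <- lapply(seq_len(K1), function(k) basis[[k]] %*% H)
  Z <- Reduce(`+`, lapply(seq_len(K1), function(k)
    TkH[[k]] %*% .thetaSlice(layer, k)))
  Z <- sweep(Z, 2L, layer$bias, "+")
  list(TkH = TkH, Z = Z)
}

#' Forward pass of the GCN
#'
#' Propagates features through the Chebyshev convolution layers
#' (recurrence T_0 = I, T_1 = L_scaled, T_k = 2 L_scaled T_{k-1} -
#' T_{k-2}), ReLU between layers and a row-wise softmax at the output.
#' With `dropoutActive`, inverted dropout is applied to the input features
#' and hidden activations (never to the softmax output).
#'
#' @param model A [GcnModel-class].
#' @param op A [SpectralOperator-class] with dimension N matching
#'   `features`.
#' @param features Numeric N x F_in matrix.
#' @param dropoutActive Apply dropout (training mode).
#' @param dropoutRate Dropout rate used when active.
#' @param seed Seed for the dropout masks.
#' @return List with `probabilities` (N x nClasses, rows summing to 1) and
#'   `cache` (intermediates for the backward pass).
#' @export
gcnForward <- function(model, op, features, dropoutActive = FALSE,
                       dropoutRate = 0, seed = 1L) {
  features <- as.matrix(features)
  basis <- if (!is.null(attr(op, "basisCache")) &&
               length(attr(op, "basisCache")) >= model@K + 1L)
    attr(op, "basisCache")[seq_len(model@K + 1L)]
  else chebyshevBasis(op, model@K)
  stopifnot2(nrow(basis[[1L]]) == nrow(features),
             "operator dimension must match the number of feature rows")
  stopifnot2(dim(model@layers[[1L]]$theta)[2L] == ncol(features),
             "feature dimension must match the model input width")
  nLayers <- length(model@layers)
  layerCaches <- vector("list", nLayers)
  H <- features
  maskSeed <- seed
  for (l in seq_len(nLayers)) {
    mask <- NULL
    if (dropoutActive && dropoutRate > 0) {
      mask <- withSeed(childSeed(maskSeed, l),
                       matrix(as.numeric(stats::runif(length(H)) >=
                                           dropoutRate) / (1 - dropoutRate),
                              nrow(H), ncol(H)))
      H <- H * mask
    }
    fw <- .layerForward(basis, H, model@layers[[l]])
    layerCaches[[l]] <- list(input = H, mask = mask, TkH = fw$TkH, Z = fw$Z)
    H <- if (l < nLayers) relu(fw$Z) else rowSoftmax(fw$Z)
  }
  list(probabilities = H,
       cache = list(basis = basis, layers = layerCaches, features = features,
                    probabilities = H))
}

## Backward pass from dLoss/dZ at the output layer. Returns parameter
## gradients and the gradient with respect to the input features.
## T_k(L_scaled) is symmetric, so its adjoint is itself.
.gcnBackward <- function(model, cache, dZ) {
  nLayers <- length(model@layers)
  basis <- cache$basis
  grads <- vector("list", nLayers)
  for (l in rev(seq_len(nLayers))) {
    lc <- cache$layers[[l]]
    layer <- model@layers[[l]]
    K1 <- dim(layer$theta)[1L]
    dTheta <- array(0, dim = dim(layer$theta))
    for (k in seq_len(K1))
      dTheta[k, , ] <- crossprod(lc$TkH[[k]], dZ)
    dBias <- colSums(dZ)
    dH <- Reduce(`+`, lapply(seq_len(K1), function(k)
      basis[[k]] %*% tcrossprod(dZ, .thetaSlice(layer, k))))
    if (!is.null(lc$mask)) dH <- dH * lc$mask
    grads[[l]] <- list(theta = dTheta, bias = dBias)
    if (l > 1L) {
      dZ <- dH * (cache$layers[[l - 1L]]$Z > 0)   # ReLU derivative
    } else {
      dFeatures <- dH
    }
  }
  list(layers = grads, dFeatures = dFeatures)
}

## One-hot label matrix over .labelLevels; unlabeled rows are all-zero.
.oneHot <- function(labels, n, nClasses) {
  Y <- matrix(0, n, nClasses)
  if (is.numeric(labels)) {
    cls <- as.integer(labels) + 1L            # 0/1 coding, 1 = MDD
  } else {
    cls <- as.integer(normalizeLabels(labels))
  }
  ok <- !is.na(cls)
  Y[cbind(which(ok), cls[ok])] <- 1
  Y
}

## Loss (mean cross-entropy over labeled vertices + (wd/2) sum theta^2) and
## gradients for one (possibly dropout-active) forward pass.
.gcnLossGrad <- function(model, op, features, labels, labeledMask,
                         weightDecay, dropoutActive = FALSE,
                         dropoutRate = 0, seed = 1L) {
  fw <- gcnForward(model, op, features, dropoutActive = dropoutActive,
                   dropoutRate = dropoutRate, seed = seed)
  P <- fw$probabilities
  n <- nrow(P)
  Y <- .oneHot(labels, n, model@nClasses)
  labeled <- which(labeledMask)
  stopifnot2(length(labeled) > 0L, "labeled mask must be non-empty")
  eps <- 1e-12
  ce <- -mean(log(pmax(P[labeled, , drop = FALSE], eps))[
    Y[labeled, , drop = FALSE] == 1])
  reg <- 0.5 * weightDecay *
    sum(vapply(model@layers, function(l) sum(l$theta^2), 0))
  dZ <- P - Y
  dZ[-labeled, ] <- 0
  dZ <- dZ / length(labeled)
  bk <- .gcnBackward(model, fw$cache, dZ)
  if (weightDecay > 0) {
    for (l in seq_along(bk$layers))
      bk$layers[[l]]$theta <- bk$layers[[l]]$theta +
        weightDecay * model@layers[[l]]$theta
  }
  list(loss = ce + reg, crossEntropy = ce, grads = bk$layers,
       probabilities = P, dFeatures = bk$dFeatures)
}

## Parameter-vector helpers (used by the optimizer and gradient checks).
.paramsToVector <- function(layers) {
  unlist(lapply(layers, function(l) c(as.numeric(l$theta), l$bias)))
}

.vectorToParams <- function(model, v) {
  pos <- 0L
  layers <- model@layers
  for (l in seq_along(layers)) {
    nTheta <- length(layers[[l]]$theta)
    layers[[l]]$theta <- array(v[pos + seq_len(nTheta)],
                               dim = dim(layers[[l]]$theta))
    pos <- pos + nTheta
    nb <- length(layers[[l]]$bias)
    layers[[l]]$bias <- v[pos + seq_len(nb)]
    pos <- pos + nb
  }
  model@layers <- layers
  model
}

#' Train the GCN transductively
#'
#' Minimizes the mean cross-entropy over the labeled (training) vertices
#' plus the l2 penalty on filter coefficients, by full-batch gradient
#' descent (or Adam). All N vertices -- including unlabeled test vertices
#' -- participate in the convolutions; their labels are never touched.
#' The recorded loss trajectory is evaluated with dropout disabled, once
#' per epoch, so it reflects the deterministic training objective.
#'
#' @param model A [GcnModel-class].
#' @param op A [SpectralOperator-class].
#' @param features Numeric N x F_in matrix.
#' @param labels Length-N label vector (`MDD`/`HC`, 0/1, or NA for
#'   unlabeled vertices).
#' @param labeledMask Logical length-N vector marking training vertices;
#'   must include both classes.
#' @param config A [trainConfig()].
#' @return List with `model` (trained) and `lossTrajectory` (per-epoch
#'   deterministic training loss).
#' @export
trainGcn <- function(model, op, features, labels, labeledMask,
                     config = trainConfig()) {
  features <- as.matrix(features)
  labeled <- which(labeledMask)
  labVals <- if (is.numeric(labels)) labels[labeled] else
    as.character(labels[labeled])
  stopifnot2(length(unique(labVals)) == 2L,
             "labeled vertices must include both classes")
  ## cache the Chebyshev basis once for the whole training run
  basis <- chebyshevBasis(op, model@K)
  attr(op, "basisCache") <- basis
  traj <- numeric(config$epochs)
  if (config$optimizer == "adam") {
    mState <- vState <- numeric(length(.paramsToVector(model@layers)))
    b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  }
  for (epoch in seq_len(config$epochs)) {
    step <- .gcnLossGrad(model, op, features, labels, labeledMask,
                         config$weightDecay,
                         dropoutActive = config$dropout > 0,
                         dropoutRate = config$dropout,
                         seed = childSeed(config$seed, epoch))
    if (!is.finite(step$loss))
      stop(sprintf(
        "training diverged at epoch %d (loss %.4g); reduce the learning rate",
        epoch, step$loss), call. = FALSE)
    g <- .paramsToVector(step$grads)
    v <- .paramsToVector(model@layers)
    if (config$optimizer == "gd") {
      v <- v - config$learningRate * g
    } else {
      mState <- b1 * mState + (1 - b1) * g
      vState <- b2 * vState + (1 - b2) * g^2
      mHat <- mState / (1 - b1^epoch)
      vHat <- vState / (1 - b2^epoch)
      v <- v - config$learningRate * mHat / (sqrt(vHat) + epsA)
    }
    model <- .vectorToParams(model, v)
    detLoss <- .gcnLossGrad(model, op, features, labels, labeledMask,
                            config$weightDecay, dropoutActive = FALSE)
    traj[epoch] <- detLoss$loss
  }
  model@trained <- TRUE
  list(model = model, lossTrajectory = traj)
}

#' Predict class labels from a trained GCN
#'
#' Dropout is disabled; repeated calls are identical. Labels are the
#' argmax of the softmax class probabilities.
#'
#' @param model A trained [GcnModel-class].
#' @param op A [SpectralOperator-class].
#' @param features Numeric N x F_in matrix.
#' @param subjectMask Optional logical vector restricting the returned
#'   rows (e.g. the test vertices).
#' @return List with `labels` (factor `HC`/`MDD`) and `probabilities`
#'   (rows over `HC`, `MDD`).
#' @export
gcnPredict <- function(model, op, features, subjectMask = NULL) {
  if (!isTRUE(model@trained))
    warning("predicting from an untrained model", call. = FALSE)
  P <- gcnForward(model, op, features, dropoutActive = FALSE)$probabilities
  colnames(P) <- .labelLevels
  labels <- factor(.labelLevels[max.col(P, ties.method = "first")],
                   levels = .labelLevels)
  if (!is.null(subjectMask)) {
    P <- P[subjectMask, , drop = FALSE]
    labels <- labels[subjectMask]
  }
  list(labels = labels, probabilities = P)
}

#' Verify analytic GCN gradients against finite differences
#'
#' Compares the reverse-mode parameter gradients of the training loss with
#' central finite differences on a small instance.
#'
#' @param model A [GcnModel-class].
#' @param op A [SpectralOperator-class].
#' @param features Numeric N x F_in matrix (small N).
#' @param labels Length-N label vector.
#' @param labeledMask Logical mask of labeled vertices (defaults to all).
#' @param epsilon Central-difference step.
#' @param weightDecay l2 penalty used in the checked loss.
#' @return Maximum relative error over all parameters.
#' @export
gradientCheck <- function(model, op, features, labels, labeledMask = NULL,
                          epsilon = 1e-5, weightDecay = 0) {
  if (is.null(labeledMask)) labeledMask <- rep(TRUE, nrow(features))
  analytic <- .paramsToVector(
    .gcnLossGrad(model, op, features, labels, labeledMask,
                 weightDecay)$grads)
  v0 <- .paramsToVector(model@layers)
  lossAt <- function(v) {
    .gcnLossGrad(.vectorToParams(model, v), op, features, labels,
                 labeledMask, weightDecay)$loss
  }
  numeric. <- vapply(seq_along(v0), function(i) {
    vp <- v0; vp[i] <- vp[i] + epsilon
    vm <- v0; vm[i] <- vm[i] - epsilon
    (lossAt(vp) - lossAt(vm)) / (2 * epsilon)
  }, 0)
  denom <- pmax(abs(analytic) + abs(numeric.), 1e-8)
  max(abs(analytic - numeric.) / denom)
}

#' Save a GCN checkpoint as JSON metadata plus delimited parameter arrays
#'
#' @param model A [GcnModel-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeGcnCheckpoint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(K = model@K, hidden_dims = model@hiddenDims,
               n_classes = model@nClasses, trained = model@trained,
               layer_shapes = lapply(model@layers,
                                     function(l) dim(l$theta)))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  for (l in seq_along(model@layers)) {
    th <- model@layers[[l]]$theta
    utils::write.table(matrix(as.numeric(th), nrow = dim(th)[1L]),
                       file.path(dir, sprintf("theta_layer%d.tsv", l)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(t(model@layers[[l]]$bias),
                       file.path(dir, sprintf("bias_layer%d.tsv", l)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
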