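#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end experiment. Defaults follow
#' the study configuration: effective-connectivity features, automatic
#' group-LASSO penalty (0.1 x median alpha_max), LASSO selection with
#' internally cross-validated lambda, population-graph kernel width
#' sigma = 1 and age threshold gamma = 2 years, a single 16-unit hidden
#' layer with third-order Chebyshev filters, dropout 0.3, learning rate
#' 0.05, weight decay 5e-4, 200 epochs, 10-fold stratified
#' cross-validation.
#'
#' @param featureKind `"ec"` (group-sparse directed connectivity),
#'   `"fc"` (Pearson correlation upper triangle) or `"gca"`
#'   (Granger-causality matrix).
#' @param alpha Group-sparse penalty or `"auto"`.
#' @param lambda LASSO selection penalty or `"auto"`.
#' @param sigma,gamma Population-graph parameters.
#' @param hiddenDims,K GCN architecture.
#' @param dropout,learningRate,weightDecay,epochs,optimizer Training
#'   hyperparameters (see [trainConfig()]).
#' @param kFolds Number of stratified folds.
#' @param seed Master seed; all per-fold seeds derive from it.
#' @param grangerOrder Lag order for `featureKind = "gca"`.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(featureKind = c("ec", "fc", "gca"),
                           alpha = "auto", lambda = "auto", sigma = 1,
                           gamma = 2, hiddenDims = 16L, K = 3L,
                           dropout = 0.3, learningRate = 0.05,
                           weightDecay = 5e-4, epochs = 200L,
                           optimizer = "gd", kFolds = 10L, seed = 1L,
                           grangerOrder = 1L) {
  featureKind <- match.arg(featureKind)
  stopifnot2(sigma > 0, "sigma must be positive")
  stopifnot2(gamma > 0, "gamma must be positive")
  stopifnot2(kFolds >= 2L, "kFolds must be at least 2")
  structure(list(featureKind = featureKind, alpha = alpha, lambda = lambda,
                 sigma = sigma, gamma = gamma,
                 hiddenDims = as.integer(hiddenDims), K = as.integer(K),
                 dropout = dropout, learningRate = learningRate,
                 weightDecay = weightDecay, epochs = as.integer(epochs),
                 optimizer = optimizer, kFolds = as.integer(kFolds),
                 seed = as.integer(seed),
                 grangerOrder = as.integer(grangerOrder)),
            class = "PipelineConfig")
}

#' Compute the full-cohort connectivity feature matrix
#'
#' `"ec"`: one joint group-sparse fit over all subjects (unsupervised and
#' transductive -- no labels involved), vectorized to length R^2 per
#' subject. `"fc"`: per-subject Pearson correlation, upper triangle.
#' `"gca"`: per-subject Granger-causality matrix, length R^2.
#'
#' @param seriesList List of [RoiTimeSeries-class].
#' @param config A [pipelineConfig()].
#' @return List with `features` (N x D matrix), `kind` (vector layout,
#'   `"ec"` or `"fc"`), `R`, and `ecStack` (for `"ec"` only).
#' @export
connectivityFeatures <- function(seriesList, config = pipelineConfig()) {
  R <- nRois(seriesList[[1L]])
  kind <- if (config$featureKind == "fc") "fc" else "ec"
  ecStack <- NULL
  if (config$featureKind == "ec") {
    ecStack <- groupSparseEC(seriesList, solverConfig(alpha = config$alpha))
    features <- t(vapply(ecMatrices(ecStack), vectorizeConnectivity,
                         numeric(R * R), kind = "ec"))
  } else if (config$featureKind == "gca") {
    features <- t(vapply(seriesList, function(ts)
      vectorizeConnectivity(grangerEC(ts, config$grangerOrder), "ec"),
      numeric(R * R)))
  } else {
    features <- t(vapply(seriesList, function(ts)
      vectorizeConnectivity(pearsonFC(ts), "fc"),
      numeric(R * (R - 1L) / 2L)))
  }
  list(features = features, kind = kind, R = R, ecStack = ecStack)
}

## Fit the selector on training rows, relaxing lambda if the selection
## comes back empty (halving from lambda.min keeps the fit train-only).
.fitSelectorNonEmpty <- function(x, y, lambda, ids, seed) {
  model <- suppressWarnings(
    fitLassoSelector(x, y, lambda = lambda, trainIds = ids, seed = seed))
  tries <- 0L
  lam <- selectorLambda(model)
  while (length(selectedIndices(model)) == 0L && tries < 8L) {
    lam <- lam / 2
    model <- suppressWarnings(
      fitLassoSelector(x, y, lambda = lam, trainIds = ids, seed = seed))
    tries <- tries + 1L
  }
  stopifnot2(length(selectedIndices(model)) > 0L,
             "feature selection stage: no features selected at any lambda")
  model
}

#' Run the full cross-validated experiment
#'
#' Per fold: LASSO feature selection fitted on training subjects' labels
#' and features only; the population graph and the GCN convolutions use
#' all subjects' (selected) features -- transductive semi-supervised
#' learning, with test labels never seen before metric computation; the
#' GCN is trained on the training vertices and evaluated on the held-out
#' fold. Fold metrics are aggregated as mean and SD, per-fold relevance
#' scores over all subjects are averaged across the folds that selected
#' each feature, and the fold-averaged scores are thresholded at
#' mu + 1.5 sigma to produce the discriminant-connection report.
#'
#' @param cohort List with `manifest` and `series` (e.g. from
#'   [simulateCohort()], or built from [readManifest()] /
#'   [readTimeSeries()]).
#' @param config A [pipelineConfig()].
#' @param atlas Optional atlas data.frame for connection names.
#' @return List with `perFold` (data.frame of ACC/SEN/SPE/AUC and
#'   confusion totals), `mean`, `sd`, `predictions` (per-subject held-out
#'   prediction and score), `relevance` (a [RelevanceReport-class]),
#'   `selectionCounts` (folds selecting each reported feature), and
#'   `config`.
#' @export
runPipeline <- function(cohort, config = pipelineConfig(), atlas = NULL) {
  manifest <- cohort$manifest
  seriesList <- cohort$series
  stopifnot2(nrow(manifest) == length(seriesList),
             "one series per manifest row required")
  labels <- normalizeLabels(manifest$label)
  ids <- as.character(manifest$subject_id)
  feat <- connectivityFeatures(seriesList, config)
  D <- ncol(feat$features)
  folds <- stratifiedFolds(manifest, k = config$kFolds,
                           seed = childSeed(config$seed, 911L))
  perFold <- vector("list", config$kFolds)
  predictions <- data.frame(subject_id = ids, truth = labels,
                            predicted = factor(NA, levels = .labelLevels),
                            score = NA_real_, fold = NA_integer_,
                            stringsAsFactors = FALSE)
  scoreSum <- numeric(D)
  scoreSubjectSum <- matrix(0, nrow(manifest), D)
  selCount <- integer(D)
  for (f in seq_len(config$kFolds)) {
    trainMask <- ids %in% folds[[f]]$train
    testMask <- !trainMask
    selector <- .fitSelectorNonEmpty(
      feat$features[trainMask, , drop = FALSE], labels[trainMask],
      config$lambda, ids[trainMask], childSeed(config$seed, 100L + f))
    fSel <- applySelector(selector, feat$features)   # all subjects
    graph <- buildAdjacency(fSel, manifest[, c("age", "gender")],
                            sigma = config$sigma, gamma = config$gamma)
    op <- spectralOperator(graph)
    model <- initGcn(ncol(fSel), hiddenDims = config$hiddenDims,
                     K = config$K, seed = childSeed(config$seed, 200L + f))
    tc <- trainConfig(learningRate = config$learningRate,
                      dropout = config$dropout,
                      weightDecay = config$weightDecay,
                      epochs = config$epochs,
                      seed = childSeed(config$seed, 300L + f),
                      optimizer = config$optimizer)
    ## test labels are masked out during training (transductive scheme)
    trainLabels <- labels
    trainLabels[testMask] <- NA
    fit <- trainGcn(model, op, fSel, trainLabels, trainMask, tc)
    pred <- gcnPredict(fit$model, op, fSel)
    predictions$predicted[testMask] <- pred$labels[testMask]
    predictions$score[testMask] <- pred$probabilities[testMask, "MDD"]
    predictions$fold[testMask] <- f
    perFold[[f]] <- classificationMetrics(
      labels[testMask], pred$labels[testMask],
      pred$probabilities[testMask, "MDD"])
    rel <- relevanceScores(fit$model, op, fSel, targetClass = "MDD")
    selIdx <- selectedIndices(selector)
    scoreSum[selIdx] <- scoreSum[selIdx] + colMeans(rel)
    scoreSubjectSum[, selIdx] <- scoreSubjectSum[, selIdx] + rel
    selCount[selIdx] <- selCount[selIdx] + 1L
  }
  perFoldDf <- do.call(rbind, lapply(perFold, as.data.frame))
  metricCols <- c("ACC", "SEN", "SPE", "AUC")
  agg <- list(mean = colMeans(perFoldDf[metricCols], na.rm = TRUE),
              sd = apply(perFoldDf[metricCols], 2L, stats::sd,
                         na.rm = TRUE))
  union <- which(selCount > 0L)
  relReport <- NULL
  if (length(union) >= 2L) {
    avgScores <- sweep(scoreSubjectSum[, union, drop = FALSE], 2L,
                       selCount[union], "/")
    relReport <- selectDiscriminant(avgScores, featureIndices = union,
                                    R = feat$R, kind = feat$kind,
                                    atlas = atlas)
  }
  list(perFold = perFoldDf, mean = agg$mean, sd = agg$sd,
       predictions = predictions, relevance = relReport,
       selectionCounts = stats::setNames(selCount[union],
                                         as.character(union)),
       featureKind = config$featureKind, config = config)
}

#' Write a pipeline report to JSON
#'
#' Serializes the per-fold metrics, their mean and SD, the resolved
#' configuration and the discriminant-connection table. Identical config
#' and seed reproduce an identical file.
#'
#' @param report Result of [runPipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writePipelineReport <- function(report, path) {
  out <- list(
    feature_kind = report$featureKind,
    config = unclass(report$config),
    per_fold = report$perFold,
    mean = as.list(report$mean),
    sd = as.list(report$sd),
    predictions = report$predictions,
    selected_connections = if (!is.null(report$relevance))
      selectedConnections(report$relevance) else NULL,
    relevance_threshold = if (!is.null(report$relevance))
      relevanceThreshold(report$relevance) else NULL)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
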