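#' @import methods
NULL

#' ROI time-series container
#'
#' Holds one subject's T x R matrix of mean ROI signals (rows are time
#' points, columns are regions of interest) together with the repetition
#' time and optional ROI names.
#'
#' @slot subjectId Character scalar subject identifier.
#' @slot data Numeric T x R matrix of finite values, T >= 2, R >= 2.
#' @slot trSeconds Positive repetition time in seconds.
#' @slot roiNames Character vector of length R (may be empty).
#'
#' @exportClass RoiTimeSeries
setClass("RoiTimeSeries",
  representation(subjectId = "character", data = "matrix",
                 trSeconds = "numeric", roiNames = "character"))

setValidity("RoiTimeSeries", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("data must be a numeric matrix")
  if (nrow(d) < 2L) return("need T >= 2 time points")
  if (ncol(d) < 2L) return("need R >= 2 ROIs")
  if (any(!is.finite(d))) return("data contains non-finite values")
  if (length(object@trSeconds) != 1L || !is.finite(object@trSeconds) ||
      object@trSeconds <= 0) return("trSeconds must be a positive scalar")
  if (length(object@roiNames) > 0L &&
      length(object@roiNames) != ncol(d))
    return("roiNames length must equal the number of ROIs")
  TRUE
})

#' Construct a RoiTimeSeries
#'
#' @param data Numeric T x R matrix (rows time points, columns ROIs).
#' @param trSeconds Repetition time in seconds.
#' @param subjectId Subject identifier.
#' @param roiNames Optional character vector of ROI names.
#' @return A [RoiTimeSeries-class] object.
#' @examples
#' ts <- RoiTimeSeries(matrix(rnorm(40), 10, 4), trSeconds = 2)
#' nTimepoints(ts); nRois(ts)
#' @export
RoiTimeSeries <- function(data, trSeconds, subjectId = "subject",
                          roiNames = character()) {
  new("RoiTimeSeries", subjectId = as.character(subjectId),
      data = as.matrix(data), trSeconds = as.numeric(trSeconds),
      roiNames = as.character(roiNames))
}

#' Per-subject stack of directed effective-connectivity matrices
#'
#' One R x R matrix per subject; entry (j, r) is the coefficient of source
#' ROI j in the sparse regression of destination ROI r. The diagonal is
#' structurally zero and all subjects share a common sparsity support.
#'
#' @slot matrices List of N numeric R x R matrices.
#' @slot subjectIds Character vector of length N.
#' @slot alpha Non-negative regularization magnitude used in the fit.
#' @slot supportMask Logical R x R matrix; TRUE where any subject's entry
#'   is nonzero.
#' @slot converged Logical vector, one flag per destination ROI.
#'
#' @exportClass EcStack
setClass("EcStack",
  representation(matrices = "list", subjectIds = "character",
                 alpha = "numeric", supportMask = "matrix",
                 converged = "logical"))

setValidity("EcStack", function(object) {
  for (m in object@matrices) {
    if (!is.matrix(m) || nrow(m) != ncol(m))
      return("all matrices must be square")
    if (any(!is.finite(m))) return("matrices contain non-finite values")
    if (any(diag(m) != 0)) return("diagonal entries must be exactly zero")
  }
  if (length(object@matrices) != length(object@subjectIds))
    return("one subject id per matrix required")
  nz <- Reduce(`|`, lapply(object@matrices, function(m) m != 0))
  if (length(object@matrices) && any(nz & !object@supportMask))
    return("supportMask must cover every nonzero entry")
  if (object@alpha < 0) return("alpha must be non-negative")
  TRUE
})

#' Pearson functional-connectivity matrix
#'
#' @slot matrix Symmetric R x R correlation matrix with unit diagonal.
#' @slot subjectId Character scalar.
#' @exportClass FcMatrix
setClass("FcMatrix",
  representation(matrix = "matrix", subjectId = "character"))

setValidity("FcMatrix", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (max(abs(m - t(m))) > 1e-12) return("matrix must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-12) return("diagonal must equal 1")
  if (any(m < -1 - 1e-12 | m > 1 + 1e-12))
    return("entries must lie in [-1, 1]")
  TRUE
})

#' Fitted LASSO feature-selector
#'
#' Stores the penalty, the indices of features retained from the full
#' connectivity vector, their coefficients, and the training-fold
#' standardization parameters frozen at fit time.
#'
#' @slot lambda Non-negative penalty actually used.
#' @slot selectedIndices Strictly increasing integer indices into the full
#'   feature vector.
#' @slot coefficients Nonzero coefficients over the selected indices.
#' @slot trainIds Character subject ids the model was fitted on.
#' @slot center,scale Standardization parameters for all D input columns.
#' @slot nFeatures Full input dimension D.
#' @exportClass SelectorModel
setClass("SelectorModel",
  representation(lambda = "numeric", selectedIndices = "integer",
                 coefficients = "numeric", trainIds = "character",
                 center = "numeric", scale = "numeric",
                 nFeatures = "integer"))

setValidity("SelectorModel", function(object) {
  idx <- object@selectedIndices
  if (length(idx) && any(diff(idx) <= 0L))
    return("selectedIndices must be strictly increasing")
  if (length(idx) && (min(idx) < 1L || max(idx) > object@nFeatures))
    return("selectedIndices out of range")
  if (length(idx) != length(object@coefficients))
    return("one coefficient per selected index required")
  if (length(idx) && any(object@coefficients == 0))
    return("coefficients of selected features must be nonzero")
  TRUE
})

#' Subject population graph
#'
#' N x N non-negative symmetric adjacency whose entries combine a Gaussian
#' similarity of imaging feature vectors with agreement indicators over
#' phenotypic measures (gender match, age difference below `gamma`).
#'
#' @slot adjacency Symmetric non-negative N x N matrix, zero diagonal.
#' @slot sigma Positive Gaussian kernel width.
#' @slot gamma Positive age-difference threshold in years.
#' @slot phenotypes data.frame with columns age and gender (one row per
#'   subject).
#' @slot featureMatrix Numeric N x m matrix used for the similarity kernel.
#' @exportClass PopulationGraph
setClass("PopulationGraph",
  representation(adjacency = "matrix", sigma = "numeric", gamma = "numeric",
                 phenotypes = "data.frame", featureMatrix = "matrix"))

setValidity("PopulationGraph", function(object) {
  w <- object@adjacency
  if (nrow(w) != ncol(w)) return("adjacency must be square")
  if (max(abs(w - t(w))) > 1e-12) return("adjacency must be symmetric")
  if (any(w < 0)) return("adjacency entries must be non-negative")
  if (any(diag(w) != 0)) return("adjacency diagonal must be zero")
  if (nrow(object@phenotypes) != nrow(w))
    return("one phenotype row per vertex required")
  TRUE
})

#' Spectral operators of a population graph
#'
#' Symmetric-normalized Laplacian, its largest eigenvalue, and the rescaled
#' operator (2/lambda_max) L - I whose spectrum lies in [-1, 1], the domain
#' of the Chebyshev filter basis.
#'
#' @slot laplacianNormalized Symmetric PSD N x N matrix.
#' @slot lambdaMax Largest eigenvalue of the normalized Laplacian.
#' @slot laplacianScaled Rescaled operator with spectrum in [-1, 1].
#' @exportClass SpectralOperator
setClass("SpectralOperator",
  representation(laplacianNormalized = "matrix", lambdaMax = "numeric",
                 laplacianScaled = "matrix"))

setValidity("SpectralOperator", function(object) {
  L <- object@laplacianNormalized
  if (max(abs(L - t(L))) > 1e-10) return("Laplacian must be symmetric")
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) return("normalized Laplacian must be PSD")
  evs <- eigen(object@laplacianScaled, symmetric = TRUE,
               only.values = TRUE)$values
  if (min(evs) < -1 - 1e-8 || max(evs) > 1 + 1e-8)
    return("scaled spectrum must lie in [-1, 1]")
  TRUE
})

#' Chebyshev spectral graph convolutional network
#'
#' Each layer holds a (K+1) x F_in x F_out coefficient tensor (one F_in x
#' F_out matrix per Chebyshev basis order) and an F_out bias vector. Hidden
#' layers use ReLU; the output layer is a 2-class softmax.
#'
#' @slot layers List of layers, each a list(theta = 3-d array, bias =
#'   numeric vector).
#' @slot K Chebyshev polynomial order (K >= 0; K+1 basis terms).
#' @slot hiddenDims Integer vector of hidden-layer widths (may be empty).
#' @slot nClasses Number of output classes (2).
#' @slot trained Logical flag set by [trainGcn()].
#' @exportClass GcnModel
setClass("GcnModel",
  representation(layers = "list", K = "integer", hiddenDims = "integer",
                 nClasses = "integer", trained = "logical"))

setValidity("GcnModel", function(object) {
  if (object@K < 0L) return("K must be non-negative")
  dims <- c(vapply(object@layers, function(l) dim(l$theta)[2L], 1),
            object@nClasses)
  for (i in seq_along(object@layers)) {
    th <- object@layers[[i]]$theta
    if (length(dim(th)) != 3L || dim(th)[1L] != object@K + 1L)
      return("theta must be a (K+1) x F_in x F_out array")
    if (dim(th)[3L] != dims[i + 1L])
      return("layer output width inconsistent with the next layer")
    if (length(object@layers[[i]]$bias) != dim(th)[3L])
      return("bias length must equal F_out")
  }
  TRUE
})

#' Sensitivity-analysis relevance report
#'
#' Per-subject absolute gradients of the target-class probability with
#' respect to each input feature, their subject means, the mu + 1.5 sigma
#' selection threshold, and the retained features mapped to directed
#' source-to-destination ROI connections.
#'
#' @slot perSubject Non-negative N x m score matrix.
#' @slot meanScores Length-m vector of subject-mean scores.
#' @slot mu,sigmaRel Mean and population SD of `meanScores`.
#' @slot threshold mu + 1.5 * sigmaRel.
#' @slot selected data.frame (featureIndex, source, destination, sourceName,
#'   destName, score) sorted by descending score.
#' @exportClass RelevanceReport
setClass("RelevanceReport",
  representation(perSubject = "matrix", meanScores = "numeric",
                 mu = "numeric", sigmaRel = "numeric", threshold = "numeric",
                 selected = "data.frame"))

setValidity("RelevanceReport", function(object) {
  if (any(object@perSubject < 0)) return("scores must be non-negative")
  if (abs(object@threshold - (object@mu + 1.5 * object@sigmaRel)) > 1e-12)
    return("threshold must equal mu + 1.5 * sigmaRel")
  s <- object@selected$score
  if (length(s) > 1L && any(diff(s) > 0))
    return("selected connections must be sorted by descending score")
  TRUE
})

#' @describeIn RoiTimeSeries-class Display a brief summary.
#' @param object A RoiTimeSeries.
#' @export
setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries '%s': %d time points x %d ROIs (TR %.3g s)\n",
              object@subjectId, nrow(object@data), ncol(object@data),
              object@trSeconds))
})

#' @describeIn EcStack-class Display a brief summary.
#' @param object An EcStack.
#' @export
setMethod("show", "EcStack", function(object) {
  r <- if (length(object@matrices)) nrow(object@matrices[[1L]]) else 0L
  cat(sprintf(
    "EcStack: %d subjects, %d x %d directed EC, alpha = %.4g, %d/%d off-diagonal connections in support\n",
    length(object@matrices), r, r, object@alpha,
    sum(object@supportMask), max(r * (r - 1L), 0L)))
})

#' @describeIn PopulationGraph-class Display a brief summary.
#' @param object A PopulationGraph.
#' @export
setMethod("show", "PopulationGraph", function(object) {
  cat(sprintf(
    "PopulationGraph: %d subjects, %d weighted edges, sigma = %.3g, gamma = %.3g\n",
    nrow(object@adjacency), sum(object@adjacency[upper.tri(object@adjacency)] > 0),
    object@sigma, object@gamma))
})

#' @describeIn GcnModel-class Display a brief summary.
#' @param object A GcnModel.
#' @export
setMethod("show", "GcnModel", function(object) {
  widths <- vapply(object@layers, function(l) dim(l$theta)[3L], 1L)
  cat(sprintf(
    "GcnModel: K = %d, layer widths [%s], %strained\n", object@K,
    paste(widths, collapse = ", "),
    if (isTRUE(object@trained)) "" else "un"))
})

#' @describeIn RelevanceReport-class Display a brief summary.
#' @param object A RelevanceReport.
#' @export
setMethod("show", "RelevanceReport", function(object) {
  cat(sprintf(
    "RelevanceReport: %d features, threshold mu + 1.5 sigma = %.4g, %d selected\n",
    length(object@meanScores), object@threshold, nrow(object@selected)))
})
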