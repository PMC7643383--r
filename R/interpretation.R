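#' Gradient sensitivity scores of the GCN prediction
#'
#' For each subject n and input feature d, computes the absolute partial
#' derivative of the target-class softmax probability for subject n with
#' respect to that subject's own feature value, all other subjects'
#' features held fixed (one reverse-mode pass per subject through the full
#' transductive forward graph, dropout disabled). The l1 norm of the
#' per-feature gradient -- its absolute value -- is the relevance score: a
#' high score means a small change in that connectivity value moves the
#' diagnosis.
#'
#' @param model A trained [GcnModel-class].
#' @param op A [SpectralOperator-class].
#' @param features Numeric N x m matrix (the selected feature matrix fed
#'   to the classifier).
#' @param targetClass `"MDD"` (default) differentiates the MDD
#'   probability; `"predicted"` uses each subject's own predicted class.
#' @return Non-negative N x m score matrix.
#' @export
relevanceScores <- function(model, op, features,
                            targetClass = c("MDD", "predicted")) {
  targetClass <- match.arg(targetClass)
  if (!isTRUE(model@trained))
    warning("computing relevance scores from an untrained model",
            call. = FALSE)
  features <- as.matrix(features)
  fw <- gcnForward(model, op, features, dropoutActive = FALSE)
  P <- fw$probabilities
  n <- nrow(features)
  classIdx <- if (targetClass == "MDD")
    rep(match("MDD", .labelLevels), n) else max.col(P, ties.method = "first")
  scores <- matrix(0, n, ncol(features))
  for (i in seq_len(n)) {
    c <- classIdx[i]
    ## d p_ic / d z_ij = p_ic (delta_jc - p_ij); other rows of Z do not
    ## feed subject i's softmax row
    dZ <- matrix(0, n, model@nClasses)
    dZ[i, ] <- P[i, c] * ((seq_len(model@nClasses) == c) - P[i, ])
    bk <- .gcnBackward(model, fw$cache, dZ)
    scores[i, ] <- abs(bk$dFeatures[i, ])
  }
  scores
}

#' Threshold mean relevance scores and map them to connections
#'
#' Averages the per-subject scores, then selects the features whose mean
#' score strictly exceeds mu + 1.5 sigma, where mu and sigma are the mean
#' and population standard deviation of the m mean scores. Selected
#' features are sorted by descending score and, when `featureIndices`,
#' `R` and `kind` are supplied, mapped back to (source ROI, destination
#' ROI) pairs via [mapToConnections()].
#'
#' @param scores Non-negative N x m matrix from [relevanceScores()], or a
#'   length-m vector of already-averaged scores.
#' @param featureIndices Optional length-m integer vector giving, for each
#'   column of `scores`, its index in the full connectivity vector.
#' @param R Number of ROIs (required for connection mapping).
#' @param kind `"ec"` or `"fc"` vector layout.
#' @param atlas Optional atlas data.frame (see [readAtlas()]) supplying
#'   ROI names.
#' @param sdType `"population"` (default, divisor m) or `"sample"`
#'   (divisor m - 1) for sigma.
#' @return A [RelevanceReport-class].
#' @examples
#' rep <- selectDiscriminant(rbind(c(1, 1, 1, 1, 10)))
#' relevanceThreshold(rep)   # 2.8 + 1.5 * 3.6 = 8.2
#' @export
selectDiscriminant <- function(scores, featureIndices = NULL, R = NULL,
                               kind = c("ec", "fc"), atlas = NULL,
                               sdType = c("population", "sample")) {
  kind <- match.arg(kind)
  sdType <- match.arg(sdType)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  m <- ncol(scores)
  stopifnot2(m >= 2L, "need at least 2 features to threshold")
  meanScores <- colMeans(scores)
  mu <- mean(meanScores)
  sigmaRel <- if (sdType == "population")
    sqrt(mean((meanScores - mu)^2)) else stats::sd(meanScores)
  threshold <- mu + 1.5 * sigmaRel
  sel <- which(meanScores > threshold)
  sel <- sel[order(meanScores[sel], decreasing = TRUE)]
  idx <- if (is.null(featureIndices)) seq_len(m) else
    as.integer(featureIndices)
  stopifnot2(length(idx) == m,
             "featureIndices must have one entry per score column")
  if (length(sel) && !is.null(R)) {
    conn <- mapToConnections(idx[sel], R = R, kind = kind, atlas = atlas)
    selected <- cbind(conn, score = meanScores[sel])
  } else {
    selected <- data.frame(featureIndex = idx[sel],
                           source = rep(NA_integer_, length(sel)),
                           destination = rep(NA_integer_, length(sel)),
                           sourceName = rep(NA_character_, length(sel)),
                           destName = rep(NA_character_, length(sel)),
                           score = meanScores[sel])
  }
  new("RelevanceReport", perSubject = scores, meanScores = meanScores,
      mu = mu, sigmaRel = sigmaRel, threshold = threshold,
      selected = selected)
}

#' Map feature-vector indices back to directed ROI connections
#'
#' Inverts the layouts of [vectorizeConnectivity()]. For `kind = "ec"`
#' (length R^2, destination-major), 1-based index v maps to destination
#' r = ceiling(v / R) and source j = v - (r - 1) R. For `kind = "fc"`
#' (length R(R-1)/2), the index enumerates the strictly-upper-triangular
#' pairs in row-major order.
#'
#' @param indices Integer vector of 1-based feature indices.
#' @param R Number of ROIs.
#' @param kind `"ec"` or `"fc"`.
#' @param atlas Optional atlas data.frame with `index` and `roi_name`
#'   columns.
#' @return data.frame (featureIndex, source, destination, sourceName,
#'   destName).
#' @examples
#' mapToConnections(2, R = 3, kind = "ec")    # source 2 -> destination 1
#' mapToConnections(c(1, 6441), R = 114, kind = "fc")
#' @export
mapToConnections <- function(indices, R, kind = c("ec", "fc"),
                             atlas = NULL) {
  kind <- match.arg(kind)
  indices <- as.integer(indices)
  if (kind == "ec") {
    stopifnot2(all(indices >= 1L & indices <= R * R),
               sprintf("ec indices must lie in 1..%d", R * R))
    destination <- ((indices - 1L) %/% R) + 1L
    source <- indices - (destination - 1L) * R
    stopifnot2(all(source != destination),
               "index points at a structurally-zero diagonal position")
  } else {
    nPairs <- R * (R - 1L) / 2L
    stopifnot2(all(indices >= 1L & indices <= nPairs),
               sprintf("fc indices must lie in 1..%d", nPairs))
    ## row-major upper-triangle enumeration: row i contributes R - i pairs
    rowStart <- cumsum(c(0L, (R - 1L):1L))       # pairs before row i
    source <- vapply(indices, function(v)
      max(which(rowStart < v)), 1L)
    destination <- indices - rowStart[source] + source
  }
  nameOf <- function(i) {
    if (is.null(atlas)) NA_character_ else
      atlas$roi_name[match(i, atlas$index)]
  }
  data.frame(featureIndex = indices, source = source,
             destination = destination,
             sourceName = nameOf(source), destName = nameOf(destination),
             stringsAsFactors = FALSE)
}

#' Write a relevance report as TSV plus JSON summary
#'
#' The TSV mirrors the discriminant-connection table layout (source index
#' and name, destination index and name, relevance score); the JSON
#' records mu, sigma and the threshold.
#'
#' @param report A [RelevanceReport-class].
#' @param path Output TSV path (a `.json` sidecar is written next to it).
#' @return `path`, invisibly.
#' @export
writeRelevanceReport <- function(report, path) {
  utils::write.table(report@selected, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(mu = report@mu, sigma = report@sigmaRel,
                            threshold = report@threshold,
                            n_selected = nrow(report@selected)),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
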