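#' Solver settings for group-sparse effective connectivity
#'
#' @param alpha Non-negative penalty magnitude, or `"auto"` to use
#'   0.1 times the median over destination ROIs of [alphaMax()].
#' @param maxIter Maximum proximal-gradient iterations per destination ROI.
#' @param tol Convergence tolerance on the relative objective change.
#' @param standardizeInputs Z-score predictor and response columns before
#'   solving, so the penalty is comparable across ROIs; coefficients are
#'   then in standardized units.
#' @return A list of class `SolverConfig`.
#' @export
solverConfig <- function(alpha = "auto", maxIter = 1000L, tol = 1e-6,
                         standardizeInputs = TRUE) {
  stopifnot2(identical(alpha, "auto") ||
             (is.numeric(alpha) && alpha >= 0), "alpha must be >= 0 or 'auto'")
  stopifnot2(tol > 0, "tol must be positive")
  structure(list(alpha = alpha, maxIter = as.integer(maxIter), tol = tol,
                 standardizeInputs = isTRUE(standardizeInputs)),
            class = "SolverConfig")
}

## Extract per-subject standardized design for destination ROI r.
## Returns list of per-subject lists(y, X) with X the T x (R-1) matrix of
## the other ROIs' signals.
.destProblem <- function(seriesList, r, standardize) {
  lapply(seriesList, function(ts) {
    x <- seriesData(ts)
    if (standardize) x <- zscoreColumns(x)$x
    list(y = x[, r], X = x[, -r, drop = FALSE])
  })
}

#' Smallest penalty yielding the all-zero solution
#'
#' For destination ROI `r`, the group-sparse objective has the all-zero
#' minimizer exactly when, for every candidate source ROI j, the l2 norm
#' over subjects of the gradient at zero, sqrt(sum_n (x_n^j' x_n^r)^2),
#' does not exceed the penalty. This function returns the maximum of those
#' norms; [groupSparseEC()] with `alpha` at or above it returns an all-zero
#' column for `r`.
#'
#' @param seriesList List of [RoiTimeSeries-class] sharing R.
#' @param r Destination ROI index.
#' @param standardizeInputs Z-score columns first (must match the solver
#'   setting).
#' @return Non-negative scalar.
#' @export
alphaMax <- function(seriesList, r, standardizeInputs = TRUE) {
  R <- nRois(seriesList[[1L]])
  stopifnot2(is.numeric(r) && length(r) == 1L && r >= 1 && r <= R,
             sprintf("destination index r must be in 1..%d", R))
  prob <- .destProblem(seriesList, r, standardizeInputs)
  g <- vapply(prob, function(p) as.numeric(crossprod(p$X, p$y)),
              numeric(R - 1L))
  g <- matrix(g, nrow = R - 1L)          # (R-1) x N gradient at zero
  sqrt(max(rowSums(g^2)))
}

## Objective of the group-sparse problem for one destination ROI.
## W is (R-1) x N.
.groupObjective <- function(W, gram, xty, yty, alpha) {
  fit <- 0
  for (n in seq_len(ncol(W))) {
    w <- W[, n]
    fit <- fit + 0.5 * (yty[n] - 2 * sum(w * xty[, n]) +
                          sum(w * (gram[[n]] %*% w)))
  }
  fit + alpha * sum(sqrt(rowSums(W^2)))
}

## Row-group soft-threshold: shrink each predictor row of W (one connection
## across subjects) toward zero by `thr` in l2 norm.
.groupSoftThreshold <- function(W, thr) {
  nrm <- sqrt(rowSums(W^2))
  scl <- pmax(0, 1 - thr / pmax(nrm, .Machine$double.xmin))
  W * scl
}

## Monotone FISTA on one destination problem. Returns list(W, objective
## trajectory, converged).
.solveDestination <- function(prob, alpha, maxIter, tol) {
  N <- length(prob)
  p <- ncol(prob[[1L]]$X)
  gram <- lapply(prob, function(q) crossprod(q$X))
  xty <- vapply(prob, function(q) as.numeric(crossprod(q$X, q$y)),
                numeric(p))
  xty <- matrix(xty, nrow = p)
  yty <- vapply(prob, function(q) sum(q$y^2), 0)
  L <- max(vapply(gram, function(g)
    max(eigen(g, symmetric = TRUE, only.values = TRUE)$values), 0))
  if (L <= 0) {                          # all-zero predictors
    return(list(W = matrix(0, p, N), trajectory = numeric(), converged = TRUE))
  }
  step <- 1 / L
  W <- matrix(0, p, N)
  Z <- W                                 # momentum point
  tk <- 1
  objPrev <- .groupObjective(W, gram, xty, yty, alpha)
  traj <- numeric(maxIter)
  converged <- FALSE
  gradAt <- function(V) {
    g <- vapply(seq_len(N), function(n) as.numeric(gram[[n]] %*% V[, n]),
                numeric(p))
    matrix(g, nrow = p) - xty
  }
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    cand <- .groupSoftThreshold(Z - step * gradAt(Z), alpha * step)
    objCand <- .groupObjective(cand, gram, xty, yty, alpha)
    if (objCand > objPrev) {
      ## momentum overshoot: fall back to a plain proximal step from W,
      ## which cannot increase the objective at step 1/L
      cand <- .groupSoftThreshold(W - step * gradAt(W), alpha * step)
      objCand <- .groupObjective(cand, gram, xty, yty, alpha)
      tk <- 1                            # restart momentum
    }
    tkNew <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Z <- cand + ((tk - 1) / tkNew) * (cand - W)
    tk <- tkNew
    W <- cand
    traj[iter] <- objCand
    denom <- max(abs(objPrev), 1e-12)
    if (abs(objPrev - objCand) / denom < tol) {
      converged <- TRUE
      objPrev <- objCand
      break
    }
    objPrev <- objCand
  }
  list(W = W, trajectory = traj[seq_len(iter)], converged = converged)
}

#' Group-constrained sparse effective connectivity
#'
#' For every destination ROI r, jointly fits all subjects' sparse
#' regressions of that ROI's signal on the remaining R-1 ROI signals by
#' minimizing
#' \deqn{\tfrac12 \sum_n \|x_n^r - X_n^{\setminus r} w_n^{\setminus r}\|_2^2
#'   + \alpha \sum_j \|(w_{1j},\dots,w_{Nj})\|_2,}
#' an l2,1 (group LASSO) penalty whose groups are connections shared across
#' subjects: a source ROI either predicts the destination in every subject
#' (with subject-specific weights) or in none, giving a common sparsity
#' support with inter-subject weight variability. Solved per destination by
#' a monotone FISTA (proximal gradient with group soft-thresholding, step
#' 1/L with L the largest per-subject Gram eigenvalue, momentum restarts on
#' objective increase), so the recorded objective never increases.
#'
#' @param seriesList List of [RoiTimeSeries-class], all with the same R.
#' @param config A [solverConfig()].
#' @return An [EcStack-class]: one R x R matrix per subject with entry
#'   (j, r) the coefficient of source j in the regression of destination r,
#'   structurally zero diagonal, plus the shared support mask. The list of
#'   per-destination objective trajectories is attached as attribute
#'   `"trajectories"`.
#' @examples
#' fix <- simulateRegressionFixture(T = 60, R = 5, sparsity = 2,
#'                                  noiseSd = 0.05, nSubjects = 3, seed = 1)
#' ec <- groupSparseEC(fix$series, solverConfig(alpha = 0.5))
#' supportMask(ec)
#' @export
groupSparseEC <- function(seriesList, config = solverConfig()) {
  stopifnot2(length(seriesList) >= 1L, "need at least one subject")
  Rs <- vapply(seriesList, nRois, 1L)
  stopifnot2(length(unique(Rs)) == 1L,
             "all subjects must share the same number of ROIs")
  R <- Rs[1L]
  N <- length(seriesList)
  alpha <- config$alpha
  if (identical(alpha, "auto")) {
    am <- vapply(seq_len(R), function(r)
      alphaMax(seriesList, r, config$standardizeInputs), 0)
    alpha <- 0.1 * stats::median(am)
  }
  mats <- lapply(seq_len(N), function(n) matrix(0, R, R))
  converged <- logical(R)
  trajectories <- vector("list", R)
  for (r in seq_len(R)) {
    prob <- .destProblem(seriesList, r, config$standardizeInputs)
    sol <- .solveDestination(prob, alpha, config$maxIter, config$tol)
    converged[r] <- sol$converged
    trajectories[[r]] <- sol$trajectory
    if (!sol$converged)
      warning(sprintf(
        "destination ROI %d: not converged after %d iterations (objective %.6g)",
        r, config$maxIter, utils::tail(sol$trajectory, 1L)))
    for (n in seq_len(N)) mats[[n]][-r, r] <- sol$W[, n]
  }
  support <- Reduce(`|`, lapply(mats, function(m) m != 0))
  ids <- vapply(seriesList, subjectId, "")
  out <- new("EcStack", matrices = mats, subjectIds = ids,
             alpha = as.numeric(alpha), supportMask = support,
             converged = converged)
  attr(out, "trajectories") <- trajectories
  out
}

#' Pearson functional connectivity
#'
#' Product-moment correlation matrix over ROI columns.
#'
#' @param ts A [RoiTimeSeries-class] with no constant column.
#' @return An [FcMatrix-class].
#' @export
pearsonFC <- function(ts) {
  x <- seriesData(ts)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds < .Machine$double.eps))
    stop(sprintf("constant ROI column(s): %s",
                 paste(which(sds < .Machine$double.eps), collapse = ", ")),
         call. = FALSE)
  m <- stats::cor(x)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  new("FcMatrix", matrix = m, subjectId = subjectId(ts))
}

#' Pairwise Granger-causality effective connectivity
#'
#' For each ordered ROI pair (j, r), fits two autoregressions of x^r_t: the
#' full model on lags 1..p of both x^r and x^j, and a restricted model on
#' the x^r lags alone, and reports the log residual-sum-of-squares ratio
#' ln(RSS_restricted / RSS_full) as a non-negative connectivity strength.
#' The diagonal is zero by convention.
#'
#' @param ts A [RoiTimeSeries-class] with T > 2 * order + 2.
#' @param order Lag order p (default 1).
#' @return Numeric R x R matrix with entry (j, r) the influence of source
#'   j on destination r.
#' @export
grangerEC <- function(ts, order = 1L) {
  order <- as.integer(order)
  stopifnot2(order >= 1L, "order must be a positive integer")
  x <- seriesData(ts)
  T <- nrow(x); R <- ncol(x)
  stopifnot2(T > 2L * order + 2L,
             sprintf("need T > 2*order + 2 = %d time points", 2L * order + 2L))
  idx <- (order + 1L):T
  lagBlock <- function(col) {
    vapply(seq_len(order), function(l) x[idx - l, col], numeric(length(idx)))
  }
  lags <- lapply(seq_len(R), lagBlock)
  out <- matrix(0, R, R)
  for (r in seq_len(R)) {
    y <- x[idx, r]
    Xr <- cbind(1, lags[[r]])
    rssR <- sum(stats::lm.fit(Xr, y)$residuals^2)
    for (j in seq_len(R)) {
      if (j == r) next
      rssF <- sum(stats::lm.fit(cbind(Xr, lags[[j]]), y)$residuals^2)
      out[j, r] <- max(0, log(rssR / max(rssF, .Machine$double.xmin)))
    }
  }
  out
}

#' Vectorize a connectivity matrix
#'
#' `kind = "ec"`: stacks the R columns of the directed matrix into a
#' length-R^2 vector (destination-major: entry (j, r) lands at index
#' (r-1)*R + j), keeping the R structural zeros so the index-to-connection
#' mapping stays trivial. `kind = "fc"`: returns the R(R-1)/2
#' strictly-upper-triangular entries in row-major order.
#'
#' @param m Square numeric matrix, or an [EcStack-class]/[FcMatrix-class]
#'   element's matrix.
#' @param kind `"ec"` or `"fc"`.
#' @return Numeric vector.
#' @examples
#' vectorizeConnectivity(diag(0, 114), "fc")  # length 6441
#' @export
vectorizeConnectivity <- function(m, kind = c("ec", "fc")) {
  kind <- match.arg(kind)
  if (is(m, "FcMatrix")) m <- fcMatrix(m)
  m <- as.matrix(m)
  stopifnot2(nrow(m) == ncol(m), "matrix must be square")
  if (kind == "ec") {
    as.numeric(m)
  } else {
    t(m)[lower.tri(m)]                   # row-major upper triangle
  }
}

#' Write a connectivity matrix with a JSON sidecar
#'
#' Writes the R x R matrix as tab-delimited text and a `<path>.json`
#' sidecar recording subject, kind, alpha and the index convention.
#'
#' @param m Square numeric matrix.
#' @param path Output path for the matrix.
#' @param subjectIdValue Subject identifier recorded in the sidecar.
#' @param kind `"ec"`, `"fc"` or `"gca"`.
#' @param alpha Penalty recorded in the sidecar (NA when not applicable).
#' @return `path`, invisibly.
#' @export
writeConnectivity <- function(m, path, subjectIdValue, kind, alpha = NA) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(subject_id = subjectIdValue, kind = kind, alpha = alpha,
               convention = "entry[j][r] = source j -> destination r")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
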