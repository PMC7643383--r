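#' Fit a LASSO feature selector
#'
#' Least-squares LASSO of 0/1 diagnostic labels (MDD = 1) on
#' column-standardized connectivity features, fitted on training subjects
#' only. The retained features are the nonzero-coefficient columns.
#' Constant columns (e.g. the structural zeros of a directed-connectivity
#' vector) carry no information and are never selected. The penalty uses
#' the glmnet parameterization, `1/(2N) RSS + lambda * ||beta||_1` on
#' standardized columns; `lambda = "auto"` picks `lambda.min` by internal
#' 5-fold cross-validation on the training subjects.
#'
#' @param features Numeric N_train x D matrix.
#' @param labels Factor or character vector of `MDD`/`HC`, or a 0/1 vector.
#' @param lambda Non-negative penalty or `"auto"`.
#' @param trainIds Optional subject ids stored in the model.
#' @param seed Seed for the internal cross-validation folds.
#' @return A [SelectorModel-class]. An empty selection (penalty too large)
#'   is returned with a warning; [applySelector()] then refuses to run.
#' @examples
#' x <- matrix(rnorm(60 * 20), 60, 20)
#' y <- rep(c(0, 1), each = 30)
#' x[, 3] <- x[, 3] + 2 * y
#' sel <- fitLassoSelector(x, y, lambda = "auto", seed = 1)
#' selectedIndices(sel)
#' @export
fitLassoSelector <- function(features, labels, lambda = "auto",
                             trainIds = character(), seed = 1L) {
  features <- as.matrix(features)
  stopifnot2(nrow(features) >= 4L, "need at least 4 training subjects")
  if (is.numeric(labels)) {
    stopifnot2(all(labels %in% c(0, 1)), "numeric labels must be 0/1")
    y <- as.numeric(labels)
  } else {
    y <- as.numeric(normalizeLabels(labels) == "MDD")
  }
  stopifnot2(length(unique(y)) == 2L,
             "both classes must be present in the training labels")
  std <- zscoreColumns(features)
  varying <- which(apply(features, 2L, stats::sd) > .Machine$double.eps)
  stopifnot2(length(varying) > 0L, "all feature columns are constant")
  xs <- std$x[, varying, drop = FALSE]
  if (identical(lambda, "auto")) {
    cv <- withSeed(seed, glmnet::cv.glmnet(
      xs, y, family = "gaussian", alpha = 1, nfolds = 5L,
      standardize = FALSE))
    lambda <- cv$lambda.min
    beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1L]
  } else {
    stopifnot2(is.numeric(lambda) && lambda >= 0, "lambda must be >= 0")
    if (lambda == 0) {
      ## unpenalized least squares (requires D <= N and full rank)
      fit <- stats::lm.fit(cbind(1, xs), y)
      stopifnot2(fit$rank == ncol(xs) + 1L,
                 "lambda = 0 requires a full-rank design with D < N")
      beta <- fit$coefficients[-1L]
    } else {
      fit <- glmnet::glmnet(xs, y, family = "gaussian", alpha = 1,
                            lambda = lambda, standardize = FALSE)
      beta <- as.numeric(fit$beta)
    }
  }
  nz <- which(abs(beta) > 0)
  if (length(nz) == 0L)
    warning("no features selected; lower lambda", call. = FALSE)
  idx <- varying[nz]
  ord <- order(idx)
  new("SelectorModel", lambda = as.numeric(lambda),
      selectedIndices = as.integer(idx[ord]),
      coefficients = as.numeric(beta[nz][ord]),
      trainIds = as.character(trainIds),
      center = std$center, scale = std$scale,
      nFeatures = ncol(features))
}

#' Apply a fitted selector to a feature matrix
#'
#' Returns the selected columns, standardized with the training-fold mean
#' and SD frozen in the model (so test subjects are transformed by
#' training-set parameters only).
#'
#' @param model A [SelectorModel-class].
#' @param features Numeric N x D matrix with D matching the fit dimension.
#' @return Numeric N x m matrix.
#' @export
applySelector <- function(model, features) {
  features <- as.matrix(features)
  stopifnot2(ncol(features) == model@nFeatures,
             sprintf("feature dimension %d does not match fit dimension %d",
                     ncol(features), model@nFeatures))
  stopifnot2(length(model@selectedIndices) > 0L,
             "selector retained no features; refit with a lower lambda")
  idx <- model@selectedIndices
  xs <- sweep(features[, idx, drop = FALSE], 2L, model@center[idx], "-")
  sweep(xs, 2L, model@scale[idx], "/")
}

#' Serialize a selector model to JSON
#'
#' @param model A [SelectorModel-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSelector <- function(model, path) {
  jsonlite::write_json(list(
    lambda = model@lambda,
    selected_indices = model@selectedIndices,
    coefficients = model@coefficients,
    train_ids = model@trainIds,
    standardization = list(center = model@center, scale = model@scale),
    n_features = model@nFeatures), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
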