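#' Simulate a synthetic rs-fMRI cohort with known directed connectivity
#'
#' Generates a cohort with the statistical structure the pipeline assumes:
#' a shared sparse directed connection skeleton, subject-level weight
#' variation around common base weights, a class-differential edge subset
#' whose weights are shifted in MDD subjects, and age/gender phenotypes.
#' ROI signals follow the instantaneous linear structural model
#' x_t = (I - A_n')^{-1} e_t with e_t ~ N(0, noiseSd^2 I), where A_n has
#' entry (j, r) = weight of source j on destination r; each A_n is
#' rescaled so its spectral radius is at most 0.9, keeping the model
#' stable. Ages are uniform integers on 20-60 (optionally shifted per
#' class), genders Bernoulli with P(F) = 0.6. Defaults mirror the study
#' scale: 29 MDD / 44 HC subjects and T = 170 time points; R defaults to
#' 20 so examples and tests stay fast (the study parcellation has
#' R = 114).
#'
#' @param nMdd,nHc Class sizes (defaults 29 and 44).
#' @param R Number of ROIs (default 20).
#' @param T Time points per subject (default 170).
#' @param density Off-diagonal support density in (0, 1) (default 0.1).
#' @param effectSize Weight shift added on class-effect edges for MDD
#'   subjects (default 1).
#' @param noiseSd Innovation SD (default 1).
#' @param trSeconds Repetition time recorded in the series (default 2).
#' @param nEffectEdges Number of class-differential edges (default: 10% of
#'   the support, at least 3).
#' @param jitterSd SD of the subject-level weight jitter around the base
#'   weights (default 0.1).
#' @param ageShift Added to MDD ages (years) to make phenotypes
#'   class-informative; default 0 (age-matched groups, as in a typical
#'   case-control design).
#' @param seed Integer seed; everything is reproducible from it.
#' @return List with `manifest` (data.frame; `series_path` empty until
#'   [writeCohort()]), `series` (list of [RoiTimeSeries-class]) and
#'   `groundTruth` (list: support, baseWeights, classEffectEdges,
#'   effectSize, subjectWeights, phenotypeRule).
#' @examples
#' cohort <- simulateCohort(nMdd = 6, nHc = 8, R = 8, T = 60, seed = 1)
#' table(cohort$manifest$label)
#' @export
simulateCohort <- function(nMdd = 29L, nHc = 44L, R = 20L, T = 170L,
                           density = 0.1, effectSize = 1, noiseSd = 1,
                           trSeconds = 2, nEffectEdges = NULL,
                           jitterSd = 0.1, ageShift = 0, seed = 1L) {
  stopifnot2(density > 0 && density < 1, "density must lie in (0, 1)")
  nEdgesTarget <- round(density * R * (R - 1L))
  stopifnot2(nEdgesTarget >= 1, "density too low: no edges would be drawn")
  N <- nMdd + nHc
  withSeed(seed, {
    offDiag <- which(diag(R) == 0)
    edgePos <- sample(offDiag, nEdgesTarget)
    support <- matrix(FALSE, R, R)
    support[edgePos] <- TRUE
    baseWeights <- matrix(0, R, R)
    baseWeights[edgePos] <- stats::runif(nEdgesTarget, 0.3, 0.8) *
      sample(c(-1, 1), nEdgesTarget, replace = TRUE)
    if (is.null(nEffectEdges))
      nEffectEdges <- max(3L, round(0.1 * nEdgesTarget))
    nEffectEdges <- min(nEffectEdges, nEdgesTarget)
    effectPos <- sample(edgePos, nEffectEdges)
    labels <- c(rep("MDD", nMdd), rep("HC", nHc))
    ids <- sprintf("sub%03d", seq_len(N))
    subjectWeights <- vector("list", N)
    series <- vector("list", N)
    for (n in seq_len(N)) {
      A <- baseWeights
      A[edgePos] <- A[edgePos] + stats::rnorm(nEdgesTarget, 0, jitterSd)
      if (labels[n] == "MDD")
        A[effectPos] <- A[effectPos] + effectSize
      ## stabilize: spectral radius of the mixing matrix at most 0.9
      rho <- max(Mod(eigen(t(A), only.values = TRUE)$values))
      if (rho > 0.9) A <- A * (0.9 / rho)
      rho2 <- max(Mod(eigen(t(A), only.values = TRUE)$values))
      if (rho2 > 0.9 + 1e-8)
        stop("internal error: unstable mixing matrix after rescaling")
      subjectWeights[[n]] <- A
      E <- matrix(stats::rnorm(T * R, 0, noiseSd), T, R)
      X <- E %*% solve(diag(R) - A)      # rows x_t' = e_t' (I - A)^{-1}
      series[[n]] <- RoiTimeSeries(X, trSeconds = trSeconds,
                                   subjectId = ids[n])
    }
    age <- as.integer(round(stats::runif(N, 20, 60)))
    age[labels == "MDD"] <- age[labels == "MDD"] + as.integer(ageShift)
    gender <- ifelse(stats::runif(N) < 0.6, "F", "M")
    manifest <- data.frame(subject_id = ids,
                           label = factor(labels, levels = .labelLevels),
                           age = age,
                           gender = factor(gender, levels = c("F", "M")),
                           series_path = "", stringsAsFactors = FALSE)
    list(manifest = manifest, series = series,
         groundTruth = list(
           support = support, baseWeights = baseWeights,
           classEffectEdges = data.frame(
             source = arrayInd(effectPos, c(R, R))[, 1L],
             destination = arrayInd(effectPos, c(R, R))[, 2L]),
           effectPositions = effectPos,
           effectSize = effectSize, subjectWeights = subjectWeights,
           phenotypeRule = sprintf(
             "age ~ round(U(20,60)) + %s*MDD; gender ~ Bernoulli(0.6 F)",
             ageShift)))
  })
}

#' Simulate a single-destination sparse-regression fixture
#'
#' Generates the exact data model of the group-sparse estimator for one
#' target ROI: per subject, R - 1 i.i.d. standard-normal predictor columns
#' and a response equal to the sparse linear combination (shared support
#' of size `sparsity`, subject-specific weights) plus Gaussian noise. The
#' response is stored as ROI column 1 so the target problem is
#' `groupSparseEC(..., r = 1)`.
#'
#' @param T Time points per subject.
#' @param R Number of ROIs (target plus R - 1 predictors).
#' @param sparsity Number of truly active predictors (< R).
#' @param noiseSd Response noise SD (0 gives a noiseless fixture).
#' @param nSubjects Number of subjects sharing the support.
#' @param seed Integer seed.
#' @param weightRange Magnitude range of true weights (default 0.5-1.5).
#' @return List with `series` (list of [RoiTimeSeries-class]),
#'   `coefficients` ((R-1) x N matrix of true weights over predictor
#'   columns 2..R) and `activeSet` (indices into 2..R of active
#'   predictors, as predictor positions 1..R-1).
#' @export
simulateRegressionFixture <- function(T, R, sparsity, noiseSd = 0,
                                      nSubjects = 1L, seed = 1L,
                                      weightRange = c(0.5, 1.5)) {
  stopifnot2(sparsity < R, "sparsity must be below R")
  withSeed(seed, {
    active <- sort(sample.int(R - 1L, sparsity))
    coef <- matrix(0, R - 1L, nSubjects)
    series <- vector("list", nSubjects)
    for (n in seq_len(nSubjects)) {
      w <- numeric(R - 1L)
      w[active] <- stats::runif(sparsity, weightRange[1L], weightRange[2L]) *
        sample(c(-1, 1), sparsity, replace = TRUE)
      coef[, n] <- w
      X <- matrix(stats::rnorm(T * (R - 1L)), T, R - 1L)
      y <- X %*% w + stats::rnorm(T, 0, noiseSd)
      series[[n]] <- RoiTimeSeries(cbind(y, X), trSeconds = 2,
                                   subjectId = sprintf("fix%02d", n))
    }
    list(series = series, coefficients = coef, activeSet = active)
  })
}

#' Write a simulated cohort to disk
#'
#' Writes the manifest CSV, one tab-delimited series file per subject, and
#' a ground-truth JSON (support, base weights, class-effect edge list,
#' effect size).
#'
#' @param cohort Result of [simulateCohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- cohort$manifest
  paths <- file.path(dir, paste0(manifest$subject_id, ".tsv"))
  for (i in seq_along(cohort$series))
    writeTimeSeries(cohort$series[[i]], paths[i])
  manifest$series_path <- paths
  manifestPath <- file.path(dir, "manifest.csv")
  writeManifest(manifest, manifestPath)
  gt <- cohort$groundTruth
  jsonlite::write_json(list(
    support = which(gt$support), base_weights = gt$baseWeights[gt$support],
    class_effect_positions = gt$effectPositions,
    effect_size = gt$effectSize),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifestPath)
}

#' Simulate a VAR(1) cohort for lagged-causality checks
#'
#' Companion generator for testing Granger-causality estimation: signals
#' follow x_t = A' x_{t-1} + e_t with the same entry convention (A[j, r]
#' is the lagged influence of source j on destination r).
#'
#' @param A R x R coefficient matrix (spectral radius of A' below 1).
#' @param T Time points.
#' @param noiseSd Innovation SD.
#' @param seed Integer seed.
#' @param burn Burn-in samples discarded (default 100).
#' @return A [RoiTimeSeries-class].
#' @export
simulateVar1 <- function(A, T, noiseSd = 1, seed = 1L, burn = 100L) {
  A <- as.matrix(A)
  R <- nrow(A)
  rho <- max(Mod(eigen(t(A), only.values = TRUE)$values))
  stopifnot2(rho < 1, "VAR(1) coefficient matrix must be stable")
  withSeed(seed, {
    x <- numeric(R)
    out <- matrix(0, T, R)
    for (t in seq_len(T + burn)) {
      x <- as.numeric(t(A) %*% x) + stats::rnorm(R, 0, noiseSd)
      if (t > burn) out[t - burn, ] <- x
    }
    RoiTimeSeries(out, trSeconds = 2, subjectId = "var1")
  })
}
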