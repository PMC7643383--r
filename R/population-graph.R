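#' Build the subject population graph
#'
#' Edge weight between subjects i and j:
#' \deqn{W_{ij} = \exp(-\|f_i - f_j\|^2 / (2\sigma^2)) \sum_h
#'   \delta_h(p_i^h, p_j^h),}
#' where the sum runs over phenotypic measures: an exact-match indicator
#' for gender (and any additional categorical measure supplied) and the
#' indicator of |age_i - age_j| < gamma for age. Subjects with similar
#' imaging features and matching phenotypes are therefore strongly
#' connected; differing gender together with an age gap of at least gamma
#' gives weight 0 regardless of features. Self-weights are set to 0.
#'
#' @param featureMatrix Numeric N x m matrix of per-subject imaging
#'   features (typically the LASSO-selected connectivity features).
#' @param phenotypes data.frame with columns `age` (numeric) and `gender`
#'   (factor/character); an optional `education` column is used as an
#'   additional categorical measure.
#' @param sigma Positive Gaussian kernel width (default 1).
#' @param gamma Positive age threshold in years (default 2).
#' @return A [PopulationGraph-class].
#' @examples
#' f <- matrix(rnorm(12), 6, 2)
#' ph <- data.frame(age = c(40, 41, 55, 30, 31, 40),
#'                  gender = c("F", "F", "M", "M", "F", "M"))
#' g <- buildAdjacency(f, ph)
#' adjacency(g)
#' @export
buildAdjacency <- function(featureMatrix, phenotypes, sigma = 1,
                           gamma = 2) {
  stopifnot2(is.numeric(sigma) && sigma > 0, "sigma must be positive")
  stopifnot2(is.numeric(gamma) && gamma > 0, "gamma must be positive")
  featureMatrix <- as.matrix(featureMatrix)
  n <- nrow(featureMatrix)
  stopifnot2(n >= 2L, "need at least 2 subjects")
  stopifnot2(all(c("age", "gender") %in% names(phenotypes)),
             "phenotypes must contain age and gender columns")
  stopifnot2(nrow(phenotypes) == n,
             "one phenotype row per subject required")
  stopifnot2(!anyNA(phenotypes$age) && !anyNA(phenotypes$gender),
             "phenotypes contain missing values")
  sq <- rowSums(featureMatrix^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(featureMatrix)
  d2[d2 < 0] <- 0
  kernel <- exp(-d2 / (2 * sigma^2))
  gender <- as.character(phenotypes$gender)
  delta <- outer(gender, gender, "==") +
    (abs(outer(phenotypes$age, phenotypes$age, "-")) < gamma)
  if ("education" %in% names(phenotypes)) {
    edu <- as.character(phenotypes$education)
    delta <- delta + outer(edu, edu, "==")
  }
  w <- kernel * delta
  w <- (w + t(w)) / 2
  diag(w) <- 0
  new("PopulationGraph", adjacency = w, sigma = sigma, gamma = gamma,
      phenotypes = as.data.frame(phenotypes),
      featureMatrix = featureMatrix)
}

#' Spectral operators for graph convolution
#'
#' Computes the symmetric-normalized Laplacian L = I - D^{-1/2} W D^{-1/2}
#' (isolated, zero-degree vertices become identity rows, keeping them
#' untouched by convolution), its largest eigenvalue, and the rescaled
#' operator (2/lambda_max) L - I whose eigenvalues lie in [-1, 1] -- the
#' interval on which the Chebyshev polynomial basis is defined.
#'
#' @param graph A [PopulationGraph-class] or a symmetric non-negative
#'   adjacency matrix.
#' @return A [SpectralOperator-class].
#' @export
spectralOperator <- function(graph) {
  w <- if (is(graph, "PopulationGraph")) adjacency(graph) else as.matrix(graph)
  n <- nrow(w)
  d <- rowSums(w)
  dInvSqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- diag(n) - (dInvSqrt %o% dInvSqrt) * w
  L <- (L + t(L)) / 2
  lmax <- max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (lmax <= .Machine$double.eps) lmax <- 2   # cannot occur for I - S
  Ls <- (2 / lmax) * L - diag(n)
  Ls <- (Ls + t(Ls)) / 2
  new("SpectralOperator", laplacianNormalized = L, lambdaMax = lmax,
      laplacianScaled = Ls)
}

## Dense Chebyshev basis T_0..T_K of the scaled Laplacian; cheap at cohort
## scale (N <= a few hundred) and reused across forward/backward passes.
chebyshevBasis <- function(op, K) {
  Ls <- scaledLaplacian(op)
  n <- nrow(Ls)
  basis <- vector("list", K + 1L)
  basis[[1L]] <- diag(n)
  if (K >= 1L) basis[[2L]] <- Ls
  if (K >= 2L) {
    for (k in 3L:(K + 1L))
      basis[[k]] <- 2 * (Ls %*% basis[[k - 1L]]) - basis[[k - 2L]]
  }
  basis
}

#' Write a population graph as delimited text plus JSON sidecar
#'
#' @param graph A [PopulationGraph-class].
#' @param path Output path for the N x N adjacency matrix.
#' @return `path`, invisibly.
#' @export
writeGraph <- function(graph, path) {
  utils::write.table(adjacency(graph), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  op <- spectralOperator(graph)
  jsonlite::write_json(list(
    sigma = graph@sigma, gamma = graph@gamma,
    phenotype_measures = intersect(c("age", "gender", "education"),
                                   names(graph@phenotypes)),
    lambda_max = lambdaMax(op)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
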