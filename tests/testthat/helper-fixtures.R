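# Shared fixtures, built in code at test time.

# Small random cohort-free graph: features + phenotypes -> operator.
makeOperator <- function(n = 6L, m = 3L, seed = 1L) {
  set.seed(seed)
  f <- matrix(rnorm(n * m), n, m)
  ph <- data.frame(age = sample(20:60, n, replace = TRUE),
                   gender = sample(c("F", "M"), n, replace = TRUE))
  g <- buildAdjacency(f, ph, sigma = 1, gamma = 10)
  list(graph = g, op = spectralOperator(g), features = f, phenotypes = ph)
}

# Alternating labels for n vertices.
altLabels <- function(n) rep(c("MDD", "HC"), length.out = n)

# Objective of the group-sparse problem on standardized data; independent
# reimplementation used as the brute-force oracle's objective.
groupObjectiveOracle <- function(w, Xs, ys, alpha) {
  W <- matrix(w, ncol = length(Xs))
  fit <- sum(vapply(seq_along(Xs), function(n)
    0.5 * sum((ys[[n]] - Xs[[n]] %*% W[, n])^2), 0))
  fit + alpha * sum(sqrt(rowSums(W^2)))
}

# Standardized design/response for destination ROI r of a series list.
standardizedProblem <- function(seriesList, r) {
  Xs <- lapply(seriesList, function(s)
    scale(seriesData(s))[, -r, drop = FALSE])
  ys <- lapply(seriesList, function(s) scale(seriesData(s))[, r])
  list(Xs = Xs, ys = ys)
}

# Flat coefficient vector for destination r from an EcStack ((R-1) x N).
ecDestinationVector <- function(ec, r) {
  as.numeric(vapply(ecMatrices(ec), function(m) m[-r, r],
                    numeric(nrow(ecMatrices(ec)[[1L]]) - 1L)))
}

writeTempManifest <- function(rows) {
  path <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,label,age,gender,series_path", rows), path)
  path
}
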