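## Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package internals never perturb user-level random
#' streams.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a base seed; kept well below .Machine$integer.max.
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset)) %% 2147483347)
}

## Column z-scoring with sample SD; returns list(x, center, scale).
## Constant columns get scale 1 so they map to all-zero columns.
zscoreColumns <- function(x, center = NULL, scale. = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  xc <- sweep(x, 2L, center, "-")
  if (is.null(scale.)) {
    scale. <- apply(xc, 2L, stats::sd)
    scale.[!is.finite(scale.) | scale. < .Machine$double.eps] <- 1
  }
  list(x = sweep(xc, 2L, scale., "/"), center = center, scale = scale.)
}

stopifnot2 <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

## Row-wise numerically stable softmax.
rowSoftmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

## Canonical diagnostic label levels; MDD is the positive class throughout.
.labelLevels <- c("HC", "MDD")

normalizeLabels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels[!is.na(labels)]), .labelLevels)
  stopifnot2(length(bad) == 0L,
             sprintf("unknown label(s): %s (expected MDD or HC)",
                     paste(bad, collapse = ", ")))
  factor(labels, levels = .labelLevels)
}
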