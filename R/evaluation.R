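#' Stratified k-fold partition of a cohort
#'
#' Shuffles each diagnostic class separately (seeded) and deals subjects
#' round-robin into k folds, so every fold's class proportions are within
#' one subject of the cohort proportions. The k test sets are disjoint and
#' cover all subjects.
#'
#' @param manifest Manifest data.frame (see [readManifest()]).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of k elements, each `list(train = ids, test = ids)`.
#' @export
stratifiedFolds <- function(manifest, k = 10L, seed = 1L) {
  k <- as.integer(k)
  labels <- normalizeLabels(manifest$label)
  counts <- table(labels)
  small <- names(counts)[counts < k]
  stopifnot2(length(small) == 0L,
             sprintf("class(es) smaller than k = %d: %s", k,
                     paste(small, collapse = ", ")))
  ids <- as.character(manifest$subject_id)
  fold <- integer(length(ids))
  withSeed(seed, for (cls in levels(labels)) {
    members <- which(labels == cls)
    members <- members[sample.int(length(members))]
    fold[members] <- rep_len(seq_len(k), length(members))
  })
  lapply(seq_len(k), function(f)
    list(train = ids[fold != f], test = ids[fold == f]))
}

#' Classification metrics for one fold
#'
#' MDD is the positive class. ACC = (TP+TN)/(TP+TN+FP+FN),
#' SEN = TP/(TP+FN), SPE = TN/(TN+FP); AUC is the Mann-Whitney rank
#' statistic of `scores` (probability of the positive class), with tied
#' scores averaged.
#'
#' @param truth True labels (`MDD`/`HC`).
#' @param predicted Predicted labels.
#' @param scores Numeric vector of positive-class scores (for AUC);
#'   optional.
#' @return List with ACC, SEN, SPE, AUC and the confusion counts TP, TN,
#'   FP, FN. Metrics undefined for single-class truth are NA with a
#'   warning.
#' @export
classificationMetrics <- function(truth, predicted, scores = NULL) {
  truth <- normalizeLabels(truth)
  predicted <- normalizeLabels(predicted)
  stopifnot2(length(truth) == length(predicted),
             "truth and predicted must have equal length")
  tp <- sum(truth == "MDD" & predicted == "MDD")
  tn <- sum(truth == "HC" & predicted == "HC")
  fp <- sum(truth == "HC" & predicted == "MDD")
  fn <- sum(truth == "MDD" & predicted == "HC")
  acc <- (tp + tn) / length(truth)
  sen <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no positive subjects: SEN undefined", call. = FALSE)
    NA_real_
  }
  spe <- if (tn + fp > 0) tn / (tn + fp) else {
    warning("no negative subjects: SPE undefined", call. = FALSE)
    NA_real_
  }
  auc <- NA_real_
  if (!is.null(scores)) {
    nPos <- sum(truth == "MDD"); nNeg <- sum(truth == "HC")
    if (nPos > 0 && nNeg > 0) {
      r <- rank(scores, ties.method = "average")
      auc <- (sum(r[truth == "MDD"]) - nPos * (nPos + 1) / 2) /
        (nPos * nNeg)
    }
  }
  list(ACC = acc, SEN = sen, SPE = spe, AUC = auc,
       TP = tp, TN = tn, FP = fp, FN = fn)
}

#' McNemar test comparing two classifiers on the same subjects
#'
#' Counts discordant pairs b (A correct, B wrong) and c (A wrong, B
#' correct). When b + c >= `exactThreshold`, uses the continuity-corrected
#' chi-square (|b-c| - 1)^2 / (b + c) on 1 df; otherwise the exact
#' two-sided binomial test of b successes in b + c trials at p = 1/2.
#'
#' @param truth True labels.
#' @param predA,predB The two classifiers' predictions.
#' @param exactThreshold Discordant-count cutoff between the exact and
#'   chi-square branches (default 25).
#' @return List with `statistic` (chi-square, NA on the exact branch),
#'   `p.value`, `b`, `c`, and `method`.
#' @export
mcnemarTest <- function(truth, predA, predB, exactThreshold = 25L) {
  truth <- as.character(truth)
  okA <- as.character(predA) == truth
  okB <- as.character(predB) == truth
  b <- sum(okA & !okB)
  c <- sum(!okA & okB)
  n <- b + c
  if (n == 0L)
    return(list(statistic = 0, p.value = 1, b = b, c = c,
                method = "degenerate"))
  if (n >= exactThreshold) {
    stat <- (abs(b - c) - 1)^2 / n
    list(statistic = stat,
         p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         b = b, c = c, method = "chi-square (continuity corrected)")
  } else {
    p <- min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
    list(statistic = NA_real_, p.value = p, b = b, c = c,
         method = "exact binomial")
  }
}

#' Pearson chi-square statistic of a contingency table
#'
#' Sum of (O - E)^2 / E without continuity correction;
#' dof = (rows - 1)(cols - 1).
#'
#' @param table Integer matrix of observed counts.
#' @return List with `statistic`, `dof` and `p.value`.
#' @examples
#' pearsonChiSquare(rbind(c(21, 27), c(8, 17)))  # gender table, 0.948
#' @export
pearsonChiSquare <- function(table) {
  table <- as.matrix(table)
  stopifnot2(all(rowSums(table) > 0) && all(colSums(table) > 0),
             "every row and column margin must be positive")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  stopifnot2(all(res$expected > 0), "all expected counts must be positive")
  list(statistic = unname(res$statistic), dof = unname(res$parameter),
       p.value = res$p.value)
}

#' Two-sample t statistic from summary statistics
#'
#' Pooled-variance Student t or Welch t computed from group means, SDs and
#' sizes (as printed in demographic tables).
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @param variant `"pooled"` or `"welch"`.
#' @return List with `statistic` and `df`.
#' @examples
#' twoSampleT(43.79, 13.06, 29, 39.68, 11.91, 44)$statistic  # ~1.389
#' @export
twoSampleT <- function(mean1, sd1, n1, mean2, sd2, n2,
                       variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot2(n1 >= 2 && n2 >= 2, "need n >= 2 per group")
  stopifnot2(sd1 >= 0 && sd2 >= 0, "SDs must be non-negative")
  diff <- mean1 - mean2
  if (sd1 == 0 && sd2 == 0 && diff == 0)
    return(list(statistic = 0, df = n1 + n2 - 2))
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    list(statistic = diff / sqrt(sp2 * (1 / n1 + 1 / n2)),
         df = n1 + n2 - 2)
  } else {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
    list(statistic = diff / sqrt(se2), df = df)
  }
}

#' Normal-theory confidence interval for a cross-validated sensitivity
#'
#' marginal error = z * sd / sqrt(n); CI = mean +/- marginal error.
#'
#' @param mean Mean of the fold metric.
#' @param sd Standard deviation over folds.
#' @param n Number of folds.
#' @param z Normal quantile (1.96 for 95%).
#' @return List with mean, sd, n, z, `marginalError` and `ci` (low, high).
#' @examples
#' sensitivityCi(0.566, 0.300, 10, 1.96)  # marginal error 0.186
#' @export
sensitivityCi <- function(mean, sd, n, z = 1.96) {
  stopifnot2(n >= 1, "n must be at least 1")
  stopifnot2(sd >= 0, "sd must be non-negative")
  me <- z * sd / sqrt(n)
  list(mean = mean, sd = sd, n = n, z = z, marginalError = me,
       ci = c(mean - me, mean + me))
}

#' Approximate diagnostic power for an estimated sensitivity
#'
#' Normal-approximation power that a study with `nCases` positive subjects
#' detects the sensitivity within the stated marginal error: the
#' probability that the half-width of the estimate's normal CI at level
#' `alpha` does not exceed `marginalError` is approximated by
#' pnorm(sqrt(nCases * marginalError^2 / (sens (1 - sens))) - z_alpha).
#' This is a simple large-sample approximation provided for orientation,
#' not a reimplementation of any specific published power procedure.
#'
#' @param sens Sensitivity under study.
#' @param marginalError Acceptable marginal error.
#' @param nCases Number of positive (case) subjects.
#' @param alpha Type I error rate (two-sided).
#' @return Power estimate in [0, 1].
#' @export
diagnosticPower <- function(sens, marginalError, nCases, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(sqrt(nCases * marginalError^2 / (sens * (1 - sens))) - z)
}
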