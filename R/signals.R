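#' Read a cohort manifest
#'
#' The manifest is a CSV with one row per subject and columns
#' `subject_id,label,age,gender,series_path`. Labels must be `MDD` or `HC`,
#' genders `F` or `M`, ages positive, and subject ids unique. Row order is
#' preserved.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with the five columns, `label` and `gender` as
#'   factors (levels `HC,MDD` and `F,M`).
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' writeLines(c("subject_id,label,age,gender,series_path",
#'              "s1,MDD,40,F,s1.tsv", "s2,HC,35,M,s2.tsv"), tmp)
#' readManifest(tmp)
#' @export
readManifest <- function(path) {
  stopifnot2(file.exists(path), sprintf("manifest not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("subject_id", "label", "age", "gender", "series_path")
  missing <- setdiff(required, names(df))
  stopifnot2(length(missing) == 0L,
             sprintf("manifest is missing column(s): %s",
                     paste(missing, collapse = ", ")))
  dup <- df$subject_id[duplicated(df$subject_id)]
  stopifnot2(length(dup) == 0L,
             sprintf("duplicate subject_id(s): %s",
                     paste(unique(dup), collapse = ", ")))
  df$label <- normalizeLabels(df$label)
  badGender <- setdiff(unique(df$gender), c("F", "M"))
  stopifnot2(length(badGender) == 0L,
             sprintf("unknown gender value(s): %s",
                     paste(badGender, collapse = ", ")))
  df$gender <- factor(df$gender, levels = c("F", "M"))
  age <- suppressWarnings(as.integer(df$age))
  stopifnot2(!any(is.na(age)) && all(age > 0L),
             "ages must be positive integers")
  df$age <- age
  df[required]
}

#' Write a cohort manifest
#'
#' Inverse of [readManifest()]; a round trip reproduces identical rows.
#'
#' @param manifest A manifest data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  out <- manifest
  out$label <- as.character(out$label)
  out$gender <- as.character(out$gender)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ROI time-series file
#'
#' Parses a delimited numeric text file (tab or comma separated, rows are
#' time points, columns are ROIs; no header by default) into a
#' [RoiTimeSeries-class]. Every cell must be finite; ragged rows and
#' non-numeric cells are format errors reporting the offending position.
#'
#' @param path Path to the delimited file.
#' @param trSeconds Repetition time in seconds.
#' @param subjectId Subject identifier (defaults to the file base name).
#' @param header Set to TRUE to skip one header row.
#' @return A [RoiTimeSeries-class].
#' @export
readTimeSeries <- function(path, trSeconds, subjectId = NULL,
                           header = FALSE) {
  stopifnot2(file.exists(path), sprintf("series file not found: %s", path))
  if (is.null(subjectId))
    subjectId <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  if (header) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  stopifnot2(length(lines) >= 2L, "need at least 2 time points")
  sep <- if (grepl("\t", lines[[1L]])) "\t" else if (grepl(",", lines[[1L]]))
    "," else "[[:space:]]+"
  cells <- lapply(lines, function(l) strsplit(trimws(l), sep)[[1L]])
  ncols <- lengths(cells)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[1L])[1L]
    stop(sprintf("ragged row %d: %d fields, expected %d",
                 bad, ncols[bad], ncols[1L]), call. = FALSE)
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(cells)), nrow = length(lines), byrow = TRUE))
  if (any(!is.finite(vals))) {
    pos <- which(!is.finite(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or non-finite value at row %d, column %d",
                 pos[1L], pos[2L]), call. = FALSE)
  }
  stopifnot2(ncol(vals) >= 2L, "need at least R = 2 ROI columns")
  RoiTimeSeries(vals, trSeconds = trSeconds, subjectId = subjectId)
}

#' Write a ROI time series as tab-delimited text
#'
#' @param ts A [RoiTimeSeries-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTimeSeries <- function(ts, path) {
  utils::write.table(seriesData(ts), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Preprocess a ROI time series
#'
#' Applies, in order: (1) optional nuisance regression, replacing each ROI
#' column by its residual after ordinary-least-squares projection onto the
#' confound columns plus an intercept; (2) optional zero-phase band-pass
#' filtering (4th-order Butterworth run forward and backward, so causal
#' estimates downstream see no phase distortion); (3) optional column
#' standardization to mean 0, sample SD 1.
#'
#' @param ts A [RoiTimeSeries-class].
#' @param band Numeric length-2 vector `c(low, high)` in Hz, or NULL.
#'   Requires 0 < low < high < Nyquist = 1/(2 TR).
#' @param confounds Numeric T x C matrix of nuisance regressors, or NULL.
#' @param standardize Standardize columns after the other steps.
#' @return A new [RoiTimeSeries-class].
#' @examples
#' ts <- RoiTimeSeries(matrix(rnorm(512 * 3), 512, 3), trSeconds = 2)
#' out <- preprocessSeries(ts, band = c(0.01, 0.1), standardize = TRUE)
#' @export
preprocessSeries <- function(ts, band = NULL, confounds = NULL,
                             standardize = FALSE) {
  x <- seriesData(ts)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    stopifnot2(nrow(confounds) == nrow(x),
               "confounds must have one row per time point")
    fit <- stats::lm.fit(cbind(1, confounds), x)
    x <- as.matrix(fit$residuals)
  }
  if (!is.null(band)) {
    stopifnot2(length(band) == 2L && band[1L] > 0 && band[1L] < band[2L],
               "band must be c(low, high) with 0 < low < high")
    nyquist <- 1 / (2 * trSeconds(ts))
    stopifnot2(band[2L] < nyquist,
               sprintf("high cutoff %.4g Hz must be below Nyquist %.4g Hz",
                       band[2L], nyquist))
    bf <- signal::butter(4, band / nyquist, type = "pass")
    x <- apply(x, 2L, function(col) signal::filtfilt(bf, col))
  }
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds < .Machine$double.eps)) {
      stop(sprintf("cannot standardize constant ROI column(s): %s",
                   paste(which(sds < .Machine$double.eps), collapse = ", ")),
           call. = FALSE)
    }
    x <- scale(x)
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
  }
  RoiTimeSeries(x, trSeconds = trSeconds(ts), subjectId = subjectId(ts),
                roiNames = roiNames(ts))
}

#' Read a ROI atlas label table
#'
#' Tab-separated table with columns `index` (1-based), `roi_name`,
#' `hemisphere`, `network_id` (1-17).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with those four columns, ordered by index.
#' @export
readAtlas <- function(path) {
  stopifnot2(file.exists(path), sprintf("atlas not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("index", "roi_name", "hemisphere", "network_id")
  missing <- setdiff(required, names(df))
  stopifnot2(length(missing) == 0L,
             sprintf("atlas is missing column(s): %s",
                     paste(missing, collapse = ", ")))
  df[order(df$index), required]
}
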