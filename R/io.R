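sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a regional time-series table
#'
#' Reads a TSV/CSV with one row per time point and one column per ROI;
#' the first row holds ROI names. Ragged rows, duplicate ROI names,
#' missing values and non-numeric cells are reported with their
#' location. `transposed = TRUE` declares the transposed dialect (rows =
#' ROIs); it is honoured only when stated, never guessed.
#'
#' @param path file path (`.tsv`/`.txt` tab-separated, `.csv`
#'   comma-separated).
#' @param subjectId identifier for the resulting object (default: file
#'   name without extension).
#' @param transposed is the file ROI-by-timepoint (default FALSE)?
#' @return A [TimeSeriesMatrix-class].
#' @export
readTimeSeries <- function(path, subjectId = NULL, transposed = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sep <- sep_for(path)
  nf <- utils::count.fields(path, sep = sep, quote = "")
  if (length(unique(nf)) != 1L)
    stop(sprintf("ragged table in %s: row %d has %d fields, row 1 has %d",
                 path, which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1]))
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "")
  if (anyDuplicated(colnames(raw)))
    stop(sprintf("duplicate ROI names in %s: '%s'", path,
                 colnames(raw)[duplicated(colnames(raw))][1]))
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw)), nrow(raw), ncol(raw)))
  bad <- which(is.na(vals) | as.matrix(raw) == "", arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "non-numeric or missing value in %s at data row %d, column '%s' ('%s')",
      path, bad[1, 1], colnames(raw)[bad[1, 2]], raw[bad[1, 1], bad[1, 2]]))
  colnames(vals) <- colnames(raw)
  if (is.null(subjectId))
    subjectId <- sub("\\.[^.]*$", "", basename(path))
  if (transposed) {
    TimeSeriesMatrix(t(vals), subjectId = subjectId,
                     roiNames = paste0("roi", seq_len(nrow(vals))))
  } else {
    TimeSeriesMatrix(vals, subjectId = subjectId)
  }
}

#' Write a time-series table
#'
#' @param ts a [TimeSeriesMatrix-class].
#' @param path output path (TSV).
#' @return Invisibly, `path`.
#' @export
writeTimeSeries <- function(ts, path) {
  stopifnot(is(ts, "TimeSeriesMatrix"))
  df <- as.data.frame(ts@values)
  colnames(df) <- ts@roiNames
  utils::write.table(format(df, digits = 17, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a square connectivity matrix as TSV
#'
#' ROI names appear as both header row and first column.
#'
#' @param B a [ConnectivityMatrix-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeConnectivity <- function(B, path) {
  stopifnot(is(B, "ConnectivityMatrix"))
  df <- as.data.frame(B@values)
  colnames(df) <- B@roiNames
  df <- cbind(roi = B@roiNames, format(df, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square connectivity matrix TSV
#'
#' @param path file with ROI names as header row and first column.
#' @return A [ConnectivityMatrix-class].
#' @export
readConnectivity <- function(path) {
  raw <- utils::read.table(path, sep = sep_for(path), header = TRUE,
                           check.names = FALSE, quote = "")
  roi <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (!identical(colnames(m), roi))
    stop(sprintf("connectivity table %s: header and first column disagree", path))
  dimnames(m) <- list(roi, roi)
  new("ConnectivityMatrix", values = (m + t(m)) / 2, kind = "pearson",
      roiNames = roi)
}

#' Read a gray-matter volume from NIfTI
#'
#' Accepts `.nii` or `.nii.gz`; the image is taken in stored orientation
#' (resampling belongs to upstream preprocessing) and the voxel size is
#' read from the header. 4D files are rejected.
#'
#' @param path NIfTI file.
#' @param subjectId identifier (default: file name).
#' @return A [VolumeImage-class].
#' @export
readVolume <- function(path, subjectId = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("%s: expected a 3D volume, got %d dimensions", path,
                 length(d)))
  vox <- RNifti::pixdim(img)[seq_len(3)]
  if (is.null(subjectId))
    subjectId <- sub("\\.nii(\\.gz)?$", "", basename(path))
  VolumeImage(array(as.numeric(img), dim = d), subjectId = subjectId,
              voxelSize = vox)
}

#' Write a volume as gzipped NIfTI
#'
#' @param vol a [VolumeImage-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "VolumeImage"))
  img <- RNifti::asNifti(vol@values)
  RNifti::pixdim(img) <- vol@voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and validate a cohort manifest
#'
#' The manifest is a TSV with columns `subjectId`, `label` (0/1; may be
#' missing for prediction-only cohorts) and at least one of `timeseries`
#' and `volume` (paths relative to the manifest's directory). Validation
#' is exhaustive before any file is loaded: duplicate ids, non-binary
#' labels and missing files all fail fast with the offending entry.
#'
#' @param path manifest TSV.
#' @param transposedTs declare the transposed time-series dialect.
#' @return cohort list (subjects with `subjectId`, `label`, `ts`,
#'   `volume`) suitable for [prepareCohort()].
#' @export
readCohortManifest <- function(path, transposedTs = FALSE) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  man <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  if (!"subjectId" %in% names(man)) stop("manifest lacks a subjectId column")
  if (anyDuplicated(man$subjectId))
    stop(sprintf("duplicate subject id in manifest: '%s'",
                 man$subjectId[duplicated(man$subjectId)][1]))
  if (!any(c("timeseries", "volume") %in% names(man)))
    stop("manifest needs a 'timeseries' and/or 'volume' column")
  if ("label" %in% names(man) &&
      !all(man$label %in% c(0L, 1L)))
    stop(sprintf("non-binary label for subject '%s'",
                 man$subjectId[!man$label %in% c(0L, 1L)][1]))
  base <- dirname(path)
  for (col in intersect(c("timeseries", "volume"), names(man))) {
    p <- file.path(base, man[[col]])
    missing <- !file.exists(p)
    if (any(missing))
      stop(sprintf("manifest file missing for subject '%s': %s",
                   man$subjectId[missing][1], p[missing][1]))
  }
  lapply(seq_len(nrow(man)), function(i) {
    subj <- list(subjectId = man$subjectId[i],
                 label = if ("label" %in% names(man)) man$label[i] else NA)
    if ("timeseries" %in% names(man))
      subj$ts <- readTimeSeries(file.path(base, man$timeseries[i]),
                                subjectId = man$subjectId[i],
                                transposed = transposedTs)
    if ("volume" %in% names(man))
      subj$volume <- readVolume(file.path(base, man$volume[i]),
                                subjectId = man$subjectId[i])
    subj
  })
}
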