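# Flat-file formats: the peak-list CSV dialect, feature/candidate tables,
# and the +/- detection-matrix CSV. mzML is accepted read-only through mzR
# when that package is installed.

.peaklist_cols <- c("scan_id", "rt_min", "mz", "intensity", "polarity")

#' Read a centroided peak list
#'
#' CSV dialect: header `scan_id,rt_min,mz,intensity,polarity`, one centroid
#' per row. Files ending in `.mzML` are read through the `mzR` package
#' (which must be installed); profile-mode mzML spectra are rejected since
#' the pipeline operates on centroided data.
#'
#' @param path File path.
#' @return data.frame with the five peak-list columns, ordered by scan.
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.mzML$", path, ignore.case = TRUE)) return(.read_mzml(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L && ncol(df) <= 1L)
    return(stats::setNames(
      data.frame(integer(), numeric(), numeric(), numeric(), character(),
                 stringsAsFactors = FALSE), .peaklist_cols))
  missing_cols <- setdiff(.peaklist_cols, names(df))
  if (length(missing_cols))
    stop("peak list ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(df$mz) | !is.finite(df$intensity) |
                 df$intensity < 0 | !df$polarity %in% .ww_polarities)
  if (length(bad))
    stop("malformed peak-list row at line ", bad[1L] + 1L, " of ", path)
  df[order(df$scan_id, df$mz), .peaklist_cols]
}

.read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package")
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  if (any(!is.na(hd$centroided) & !hd$centroided))
    stop("centroided input required: ", path, " contains profile spectra")
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  parts <- lapply(seq_along(pk), function(i) {
    if (nrow(pk[[i]]) == 0L) return(NULL)
    data.frame(scan_id = i, rt_min = hd$retentionTime[i] / 60,
               mz = pk[[i]][, 1L], intensity = pk[[i]][, 2L],
               polarity = ifelse(hd$polarity[i] >= 0, "positive", "negative"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

#' Write a run or peak list to the peak-list CSV dialect
#'
#' m/z is serialized at 6 decimal places; write-then-read round-trips
#' within that precision.
#'
#' @param x A `ww_run` or a peak-list data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(x, path) {
  peaks <- if (inherits(x, "ww_run")) x$peaks else as.data.frame(x)
  stopifnot(all(.peaklist_cols %in% names(peaks)))
  out <- peaks[, .peaklist_cols]
  out$mz <- sprintf("%.6f", out$mz)
  out$rt_min <- sprintf("%.4f", out$rt_min)
  out$intensity <- sprintf("%.2f", out$intensity)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a detection matrix as +/- CSV
#'
#' Serializes losslessly to a visually diffable grid: `+` detected,
#' `-` not detected, compounds as rows, `stage.protocol` as columns.
#'
#' @param dm A [detection_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_detection_matrix <- function(dm, path) {
  df <- data.frame(compound = rownames(dm),
                   ifelse(unclass(dm), "+", "-"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a +/- detection-matrix CSV
#'
#' @param path File written by [write_detection_matrix()] (or hand-edited
#'   in the same dialect).
#' @return A `ww_detection_matrix`.
#' @export
read_detection_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(names(df)[1L] == "compound")
  m <- as.matrix(df[, -1L, drop = FALSE]) == "+"
  rownames(m) <- df$compound
  class(m) <- c("ww_detection_matrix", class(m))
  m
}
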