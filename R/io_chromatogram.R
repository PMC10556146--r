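#' Construct a scan x m/z intensity matrix
#'
#' The raw chromatogram container: rows are scans (strictly increasing
#' retention times in minutes), columns are integer unit-mass m/z bins.
#'
#' @param scan_times numeric vector, minutes, strictly increasing, length >= 2.
#' @param mz_axis strictly increasing integer m/z bins.
#' @param intensities numeric matrix, `length(scan_times)` x `length(mz_axis)`,
#'   non-negative.
#' @param sample_id character scalar.
#' @param is_blank logical; blank (procedural) run?
#' @return object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(scan_times, mz_axis, intensities,
                             sample_id = "sample", is_blank = FALSE) {
  scan_times <- as.numeric(scan_times)
  mz_axis <- as.integer(round(mz_axis))
  intensities <- as.matrix(intensities)
  if (length(scan_times) < 2L)
    stop("need at least 2 scans")
  if (any(diff(scan_times) <= 0))
    stop("scan_times must be strictly increasing")
  if (length(mz_axis) < 1L || any(diff(mz_axis) <= 0))
    stop("mz_axis must be strictly increasing integers")
  if (nrow(intensities) != length(scan_times) ||
      ncol(intensities) != length(mz_axis))
    stop("intensities must be scans x m/z: ",
         length(scan_times), " x ", length(mz_axis))
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and non-negative")
  dimnames(intensities) <- NULL
  structure(list(scan_times = scan_times, mz_axis = mz_axis,
                 intensities = intensities,
                 sample_id = as.character(sample_id),
                 is_blank = isTRUE(is_blank)),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat("<intensity_matrix> ", x$sample_id,
      if (x$is_blank) " (blank)", ": ",
      length(x$scan_times), " scans x ", length(x$mz_axis), " m/z bins, rt ",
      sprintf("%.3f-%.3f", x$scan_times[1],
              x$scan_times[length(x$scan_times)]), " min\n", sep = "")
  invisible(x)
}

#' Total ion current of a chromatogram
#' @param m an [intensity_matrix()].
#' @return numeric vector, per-scan sum over all m/z bins.
#' @export
tic <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  rowSums(m$intensities)
}

#' Read a chromatogram
#'
#' Two dialects are supported. `"csv_fixture"` is a long-format text dialect
#' with columns `scan_time` (minutes), `mz`, `intensity`. `"andi_netcdf"`
#' reads ANDI-MS .cdf files through the mzR netCDF backend (variables
#' scan_acquisition_time / mass_values / intensity_values / scan_index);
#' retention times there are in seconds and are converted to minutes.
#' Fractional m/z values are rounded to the nearest unit-mass bin
#' (half away from zero) and intensities falling in the same bin summed, so
#' the total ion current of each scan is preserved.
#'
#' @param path file path.
#' @param dialect `"csv_fixture"` or `"andi_netcdf"`; default guessed from
#'   the file extension (.cdf -> netCDF).
#' @param sample_id sample identifier; default the file base name.
#' @param is_blank logical flag carried on the result.
#' @return an [intensity_matrix()].
#' @export
read_chromatogram <- function(path, dialect = NULL,
                              sample_id = NULL, is_blank = FALSE) {
  if (!file.exists(path))
    stop("chromatogram file not found: ", path)
  if (is.null(dialect))
    dialect <- if (grepl("\\.cdf$", path, ignore.case = TRUE))
      "andi_netcdf" else "csv_fixture"
  dialect <- match.arg(dialect, c("csv_fixture", "andi_netcdf"))
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]+$", "", basename(path))
  if (dialect == "csv_fixture") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("scan_time", "mz", "intensity")
    if (!all(need %in% names(df)))
      stop("csv_fixture dialect needs columns scan_time, mz, intensity: ",
           path)
    if (nrow(df) == 0L) stop("empty scan list in ", path)
    build_matrix_from_long(df$scan_time, df$mz, df$intensity,
                           sample_id, is_blank)
  } else {
    read_andi_netcdf(path, sample_id, is_blank)
  }
}

# shared assembly: long (time, mz, intensity) records -> intensity_matrix
build_matrix_from_long <- function(time, mz, intensity, sample_id, is_blank) {
  mz_bin <- round_half_away(mz)
  scan_times <- sort(unique(time))
  if (length(scan_times) < 2L)
    stop("need at least 2 scans")
  mz_axis <- sort(unique(mz_bin))
  si <- match(time, scan_times)
  mi <- match(mz_bin, mz_axis)
  X <- matrix(0, length(scan_times), length(mz_axis))
  # sum duplicates landing in the same (scan, bin) cell
  idx <- (mi - 1L) * length(scan_times) + si
  acc <- tapply(intensity, idx, sum)
  X[as.integer(names(acc))] <- as.numeric(acc)
  intensity_matrix(scan_times, mz_axis, X, sample_id, is_blank)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) trunc(x + sign(x) * 0.5)

read_andi_netcdf <- function(path, sample_id, is_blank) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading ANDI-MS netCDF requires the mzR package")
  f <- mzR::openMSfile(path, backend = "netCDF")
  on.exit(mzR::close(f), add = TRUE)
  h <- mzR::header(f)
  n <- nrow(h)
  if (n == 0L) stop("empty scan list in ", path)
  pk <- mzR::peaks(f)
  if (n == 1L) pk <- list(pk)
  times_min <- h$retentionTime / 60
  if (any(diff(times_min) <= 0))
    stop("non-monotone scan times in ", path)
  counts <- vapply(pk, nrow, integer(1))
  build_matrix_from_long(rep(times_min, counts),
                         unlist(lapply(pk, function(p) p[, 1])),
                         unlist(lapply(pk, function(p) p[, 2])),
                         sample_id, is_blank)
}

#' Write a chromatogram in the long CSV fixture dialect
#'
#' Zero cells are omitted; [read_chromatogram()] restores them. Note that
#' all-zero scans and all-zero m/z bins are therefore not round-tripped.
#'
#' @param m an [intensity_matrix()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_chromatogram_csv <- function(m, path) {
  stopifnot(inherits(m, "intensity_matrix"))
  nz <- which(m$intensities > 0, arr.ind = TRUE)
  df <- data.frame(scan_time = m$scan_times[nz[, 1]],
                   mz = m$mz_axis[nz[, 2]],
                   intensity = m$intensities[nz])
  df <- df[order(df$scan_time, df$mz), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
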