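#' Construct a sparse unit-mass spectrum
#'
#' A mass spectrum is stored sparsely as parallel vectors of integer m/z
#' bins and non-negative intensities. Bins repeat-free, sorted ascending;
#' zero-intensity bins are dropped. The cosine score in [score_ms()] treats
#' absent bins as zero on the shared integer axis 1..5000.
#'
#' @param mz integer m/z values (1..5000).
#' @param intensity non-negative intensities, same length as `mz`.
#' @return an object of class `mass_spectrum` with fields `mz`, `intensity`.
#' @examples
#' mass_spectrum(c(43, 71), c(100, 50))
#' @export
mass_spectrum <- function(mz, intensity) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  mz <- as.integer(round(mz))
  intensity <- as.numeric(intensity)
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and non-negative")
  if (any(mz < 1L) || any(mz > 5000L))
    stop("m/z bins must lie in 1..5000")
  keep <- intensity > 0
  mz <- mz[keep]; intensity <- intensity[keep]
  if (length(mz) == 0L)
    stop("spectrum has no nonzero intensity")
  # merge duplicate bins
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, mz, sum))
    mz <- sort(unique(mz))
  } else {
    o <- order(mz); mz <- mz[o]; intensity <- intensity[o]
  }
  structure(list(mz = mz, intensity = intensity), class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat("<mass_spectrum> ", length(x$mz), " peaks, base peak m/z ",
      x$mz[which.max(x$intensity)], "\n", sep = "")
  invisible(x)
}

is_mass_spectrum <- function(x) inherits(x, "mass_spectrum")

#' Densify a sparse spectrum onto an integer m/z axis
#'
#' @param s a [mass_spectrum()].
#' @param mz_max upper end of the axis (default 5000).
#' @return numeric vector of length `mz_max`; position i holds intensity at
#'   m/z i (0 where absent).
#' @export
spectrum_to_vector <- function(s, mz_max = 5000L) {
  stopifnot(is_mass_spectrum(s))
  v <- numeric(mz_max)
  v[s$mz] <- s$intensity
  v
}

#' Base peak m/z of a spectrum
#' @param s a [mass_spectrum()].
#' @return integer m/z of the most intense peak.
#' @export
base_peak <- function(s) {
  stopifnot(is_mass_spectrum(s))
  s$mz[which.max(s$intensity)]
}

# intensity at given bins (0 where absent)
spectrum_at <- function(s, mz) {
  i <- match(as.integer(mz), s$mz)
  out <- s$intensity[i]
  out[is.na(out)] <- 0
  out
}
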