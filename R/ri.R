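#' Construct an alkane calibration
#'
#' Ordered (carbon number, retention time) pairs from an n-alkane reference
#' run; the anchor points of the van den Dool-Kratz linear retention index.
#'
#' @param carbon integer carbon numbers, strictly increasing (e.g. 6..26).
#' @param rt apex retention times in minutes, strictly increasing.
#' @return object of class `alkane_calibration`.
#' @export
alkane_calibration <- function(carbon, rt) {
  carbon <- as.integer(carbon)
  rt <- as.numeric(rt)
  if (length(carbon) != length(rt) || length(carbon) < 2L)
    stop("need >= 2 (carbon, rt) pairs")
  if (any(diff(carbon) <= 0)) stop("carbon numbers must be strictly increasing")
  if (any(diff(rt) <= 0)) stop("retention times must be strictly increasing")
  structure(list(carbon = carbon, rt = rt), class = "alkane_calibration")
}

#' @export
print.alkane_calibration <- function(x, ...) {
  cat("<alkane_calibration> C", x$carbon[1], "-C",
      x$carbon[length(x$carbon)], ", rt ",
      sprintf("%.3f-%.3f", x$rt[1], x$rt[length(x$rt)]), " min\n", sep = "")
  invisible(x)
}

#' Detect the n-alkane series in a reference chromatogram
#'
#' Runs [detect_components()], keeps components whose spectra show the
#' alkane fragment ladder (base peak m/z 57 with 43, 71 and 85 present) and
#' takes the largest-area `length(expected)` of them; carbon numbers are
#' assigned in elution order starting at the low end of `expected`.
#'
#' @param m an [intensity_matrix()] of the alkane reference run.
#' @param expected integer range of carbon numbers, default `6:26`.
#' @param ... passed to [detect_components()].
#' @return an [alkane_calibration()].
#' @export
detect_alkanes <- function(m, expected = 6:26, ...) {
  comps <- detect_components(m, ...)
  ok <- vapply(comps, function(cc) {
    base_peak(cc$spectrum) == 57L &&
      all(spectrum_at(cc$spectrum, c(43L, 71L, 85L)) > 0)
  }, logical(1))
  comps <- comps[ok]
  if (length(comps) < length(expected))
    stop("alkane calibration failed: found ", length(comps), " of ",
         length(expected), " expected alkane peaks")
  areas <- vapply(comps, function(cc) cc$area, numeric(1))
  comps <- comps[order(areas, decreasing = TRUE)[seq_along(expected)]]
  rt <- sort(vapply(comps, function(cc) cc$apex_time, numeric(1)))
  alkane_calibration(expected, rt)
}

#' Linear retention index of a retention time
#'
#' Temperature-programmed (van den Dool-Kratz) index: piecewise-linear in
#' retention time with value `100 * n` at the C_n alkane apex,
#' `RI = 100*n + 100*(rt - t_n)/(t_{n+1} - t_n)` between apexes. Linear
#' extrapolation from the terminal segments is allowed up to `guard` index
#' units beyond the calibrated range; beyond that a range error is raised
#' (the +/-30 identification window makes larger extrapolations
#' meaningless).
#'
#' @param rt retention time(s), minutes.
#' @param cal an [alkane_calibration()].
#' @param guard extrapolation allowance in index units (default 50).
#' @return numeric retention index (vectorized over `rt`).
#' @export
compute_ri <- function(rt, cal, guard = 50) {
  stopifnot(inherits(cal, "alkane_calibration"))
  ri <- ri_interp(as.numeric(rt), cal$rt, 100 * cal$carbon)
  lo <- 100 * cal$carbon[1] - guard
  hi <- 100 * cal$carbon[length(cal$carbon)] + guard
  if (any(ri < lo | ri > hi))
    stop("retention time outside the calibrated range (RI ",
         paste(round(range(ri), 1), collapse = ".."), ", allowed ",
         lo, "..", hi, ")")
  ri
}

# piecewise-linear interpolation with end-segment extrapolation
ri_interp <- function(x, xs, ys) {
  n <- length(xs)
  seg <- findInterval(x, xs, all.inside = TRUE)
  ys[seg] + (ys[seg + 1] - ys[seg]) * (x - xs[seg]) / (xs[seg + 1] - xs[seg])
}

#' Retention time at a given retention index
#'
#' Inverse of [compute_ri()]: `compute_ri(invert_ri(ri, cal), cal) == ri`
#' to 1e-9 over the calibrated range (600..2600 for a C6-C26 series).
#'
#' @param ri retention index value(s).
#' @param cal an [alkane_calibration()].
#' @param guard extrapolation allowance in index units (default 50).
#' @return retention time(s) in minutes.
#' @export
invert_ri <- function(ri, cal, guard = 50) {
  stopifnot(inherits(cal, "alkane_calibration"))
  ri <- as.numeric(ri)
  lo <- 100 * cal$carbon[1] - guard
  hi <- 100 * cal$carbon[length(cal$carbon)] + guard
  if (any(ri < lo | ri > hi))
    stop("retention index outside the calibrated range (allowed ",
         lo, "..", hi, ")")
  ri_interp(ri, 100 * cal$carbon, cal$rt)
}
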