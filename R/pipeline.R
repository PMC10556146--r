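#' Detect and identify compounds in one chromatogram
#'
#' The full per-run pipeline: denoise, Biller-Biemann component detection,
#' retention-index assignment against an alkane calibration, library
#' matching at the score threshold, optional blank subtraction, and the
#' one-occurrence-per-compound rule (largest area wins).
#'
#' Blank subtraction is off by default: it is used when validating against
#' a procedural blank (model-whisky workflow) and skipped for routine
#' sample batches.
#'
#' @param m an [intensity_matrix()] (raw).
#' @param cal an [alkane_calibration()].
#' @param lib list of [library_entry()] objects.
#' @param threshold minimum combined identification score (default 0.8).
#' @param ri_window Heaviside half-width in index units (default 30).
#' @param blank optional blank compound list (a [build_sample_list()]
#'   result) for [subtract_blank()].
#' @param denoise_window,min_intensity passed to [denoise()].
#' @param apex_window,min_channels,min_area passed to
#'   [detect_components()].
#' @param ratio_min blank-subtraction area-ratio threshold (default 3).
#' @param internal_standards names expected in the run.
#' @return a `sample_compound_list` data.frame (see
#'   [build_sample_list()]).
#' @export
detect_compounds <- function(m, cal, lib, threshold = 0.8, ri_window = 30,
                             blank = NULL, denoise_window = 5,
                             min_intensity = 150, apex_window = 2,
                             min_channels = 3, min_area = 1e4,
                             ratio_min = 3,
                             internal_standards =
                               c("n-Undecane", "4-Chloro-2-methoxyphenol")) {
  md <- denoise(m, window = denoise_window, min_intensity = min_intensity)
  comps <- detect_components(md, apex_window = apex_window,
                             min_channels = min_channels,
                             min_area = min_area)
  # RI assignment; components eluting outside the calibrated+guard range
  # cannot be matched and are dropped
  ris <- rep(NA_real_, length(comps))
  for (i in seq_along(comps))
    ris[i] <- tryCatch(compute_ri(comps[[i]]$apex_time, cal),
                       error = function(e) NA_real_)
  keep <- !is.na(ris)
  sl <- build_sample_list(comps[keep], ris[keep], lib,
                          threshold = threshold, ri_window = ri_window,
                          internal_standards = internal_standards,
                          sample_id = m$sample_id)
  if (!is.null(blank))
    sl <- subtract_blank(sl, blank, ratio_min = ratio_min)
  sl
}

#' Run configuration I/O
#'
#' Reads/writes the pipeline tuning parameters (denoise.window,
#' denoise.min_intensity, deconv.apex_window, deconv.min_channels,
#' deconv.min_area, match.threshold, match.ri_window, blank.ratio_min) as
#' JSON.
#'
#' @param path JSON file path.
#' @return named list of parameters.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_run_config
#' @param config named list.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
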