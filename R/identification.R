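#' Mass-spectral cosine similarity
#'
#' Cosine of two unit-mass spectra expanded onto the shared integer m/z
#' axis (absent bins count as 0):
#' `sum(a_i * b_i) / (sqrt(sum(a_i^2)) * sqrt(sum(b_i^2)))`.
#' Symmetric, invariant to global intensity scaling, 1 iff the spectra are
#' proportional, 0 for disjoint m/z sets.
#'
#' @param a,b [mass_spectrum()] objects.
#' @return similarity in [0, 1].
#' @export
score_ms <- function(a, b) {
  stopifnot(is_mass_spectrum(a), is_mass_spectrum(b))
  # sparse dot product over the union of bins
  dot <- sum(a$intensity * spectrum_at(b, a$mz))
  na <- sqrt(sum(a$intensity^2))
  nb <- sqrt(sum(b$intensity^2))
  if (na == 0 || nb == 0) stop("cosine undefined for an all-zero spectrum")
  min(1, dot / (na * nb))
}

#' Combined mass-spectral / retention-index identification score
#'
#' The spectral cosine `s` is offset against the relative retention-index
#' mismatch: `1 - ((1 - s) + |ri_temp - ri_lib| / ri_lib) / 2`, multiplied
#' by a Heaviside window that zeroes any candidate more than 30 index
#' units from the library value. Equals `(1 + s) / 2` at an exact RI match
#' and 1 only for a perfect spectral and RI match.
#'
#' @param s spectral cosine from [score_ms()], in [0, 1].
#' @param ri_temp observed retention index of the component.
#' @param ri_lib library retention index (> 0).
#' @param ri_window half-width of the Heaviside window in index units
#'   (default 30).
#' @return combined score in [0, 1] (vectorized over `ri_temp`/`ri_lib`).
#' @export
score_ms_ri <- function(s, ri_temp, ri_lib, ri_window = 30) {
  if (any(s < 0 | s > 1)) stop("s must lie in [0, 1]")
  if (any(ri_lib <= 0)) stop("ri_lib must be positive")
  delta <- abs(ri_temp - ri_lib)
  score <- 1 - ((1 - s) + delta / ri_lib) / 2
  ifelse(delta > ri_window, 0, pmax(0, pmin(1, score)))
}

#' Score a component against a spectral library
#'
#' Every library entry is scored with [score_ms()] and [score_ms_ri()];
#' entries reaching `threshold` are returned sorted by descending combined
#' score (ties: smaller |RI delta| first, then library order) with ranks
#' assigned. An empty result means no identity is proposed.
#'
#' @param component a component from [detect_components()] (needs a
#'   `spectrum`), or a bare [mass_spectrum()].
#' @param ri observed retention index of the component.
#' @param lib list of [library_entry()] objects.
#' @param threshold minimum combined score for proposing an identity
#'   (default 0.8).
#' @param ri_window Heaviside half-width, index units (default 30).
#' @return data.frame with columns `name`, `cas`, `ri_lib`, `ri_delta`,
#'   `score_ms`, `score_ms_ri`, `rank`, `lib_index`.
#' @export
match_component <- function(component, ri, lib, threshold = 0.8,
                            ri_window = 30) {
  if (length(lib) == 0L) stop("empty library")
  spec <- if (is_mass_spectrum(component)) component else component$spectrum
  ri_lib <- vapply(lib, function(e) e$ri, numeric(1))
  delta <- abs(ri - ri_lib)
  # the RI window prunes the spectral comparisons
  in_win <- delta <= ri_window
  sms <- rep(NA_real_, length(lib))
  sms[in_win] <- vapply(lib[in_win],
                        function(e) score_ms(spec, e$spectrum), numeric(1))
  total <- numeric(length(lib))
  total[in_win] <- score_ms_ri(sms[in_win], ri, ri_lib[in_win],
                               ri_window = ri_window)
  keep <- which(total >= threshold)
  keep <- keep[order(-total[keep], delta[keep], keep)]
  data.frame(name = vapply(lib[keep], function(e) e$name, character(1)),
             cas = vapply(lib[keep], function(e) e$cas %||% NA_character_,
                          character(1)),
             ri_lib = ri_lib[keep], ri_delta = ri - ri_lib[keep],
             score_ms = sms[keep], score_ms_ri = total[keep],
             rank = seq_along(keep), lib_index = keep,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Best-match compound list of one sample run
#'
#' For each detected component the rank-1 library identity is kept (plus
#' the runner-up name/score for reporting). When one compound name is
#' proposed at several retention times, only the occurrence with the
#' largest peak area is retained, so every analyte appears at most once per
#' sample. A warning is raised when an internal standard is not matched.
#'
#' @param components a `component_list` from [detect_components()].
#' @param ris observed retention indices, one per component (e.g.
#'   `compute_ri(apex times, cal)`).
#' @param lib list of [library_entry()] objects.
#' @param threshold minimum combined score (default 0.8).
#' @param ri_window Heaviside half-width (default 30).
#' @param internal_standards compound names expected in every run.
#' @param sample_id carried onto the result.
#' @return data.frame of class `sample_compound_list`: columns `sample`,
#'   `compound`, `cas`, `rt`, `ri_observed`, `ri_lib`, `score_ms`,
#'   `score_ms_ri`, `area`, `rank2_name`, `rank2_score`.
#' @export
build_sample_list <- function(components, ris, lib, threshold = 0.8,
                              ri_window = 30,
                              internal_standards =
                                c("n-Undecane", "4-Chloro-2-methoxyphenol"),
                              sample_id = "sample") {
  stopifnot(length(components) == length(ris))
  rows <- lapply(seq_along(components), function(i) {
    mm <- match_component(components[[i]], ris[i], lib,
                          threshold = threshold, ri_window = ri_window)
    if (nrow(mm) == 0L) return(NULL)
    data.frame(sample = sample_id, compound = mm$name[1], cas = mm$cas[1],
               rt = components[[i]]$apex_time, ri_observed = ris[i],
               ri_lib = mm$ri_lib[1], score_ms = mm$score_ms[1],
               score_ms_ri = mm$score_ms_ri[1],
               area = components[[i]]$area,
               rank2_name = if (nrow(mm) > 1) mm$name[2] else NA_character_,
               rank2_score = if (nrow(mm) > 1) mm$score_ms_ri[2] else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- empty_sample_list()
  # one occurrence per compound name: keep the largest area
  if (nrow(out) > 1) {
    out <- out[order(out$compound, -out$area), ]
    out <- out[!duplicated(out$compound), ]
    out <- out[order(out$rt), ]
  }
  rownames(out) <- NULL
  missing_istd <- setdiff(internal_standards, out$compound)
  if (length(missing_istd))
    warning("internal standard(s) not detected in ", sample_id, ": ",
            paste(missing_istd, collapse = ", "))
  class(out) <- c("sample_compound_list", "data.frame")
  out
}

empty_sample_list <- function() {
  data.frame(sample = character(), compound = character(), cas = character(),
             rt = numeric(), ri_observed = numeric(), ri_lib = numeric(),
             score_ms = numeric(), score_ms_ri = numeric(), area = numeric(),
             rank2_name = character(), rank2_score = numeric(),
             stringsAsFactors = FALSE)
}

#' Remove blank contaminants from a sample compound list
#'
#' Compounds present in both the sample and the blank list whose peak-area
#' ratio (sample / blank) is smaller than `ratio_min` are removed; the rule
#' is strict, so a ratio exactly equal to `ratio_min` is kept. Compounds
#' absent from the blank are kept; compounds only in the blank are ignored.
#' A blank area of 0 is treated as ratio +Inf (kept, with a message).
#'
#' @param sample_list,blank_list data.frames with `compound` and `area`
#'   columns (as from [build_sample_list()]).
#' @param ratio_min minimum sample/blank area ratio (default 3).
#' @return the filtered `sample_list`.
#' @export
subtract_blank <- function(sample_list, blank_list, ratio_min = 3) {
  if (nrow(sample_list) == 0L || nrow(blank_list) == 0L) return(sample_list)
  b_area <- blank_list$area[match(sample_list$compound, blank_list$compound)]
  shared <- !is.na(b_area)
  ratio <- sample_list$area / b_area
  zero_blank <- shared & b_area == 0
  if (any(zero_blank)) {
    message("blank area 0 for ",
            paste(sample_list$compound[zero_blank], collapse = ", "),
            "; kept (ratio treated as +Inf)")
    ratio[zero_blank] <- Inf
  }
  drop <- shared & ratio < ratio_min
  out <- sample_list[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a sample x compound relative-area table
#'
#' Columns are the union of compound names over all sample lists; entries
#' are peak areas divided by the sample's internal-standard area (0 where a
#' compound was not detected). The internal-standard column is therefore 1
#' in every sample.
#'
#' @param sample_lists list of [build_sample_list()] results (one per
#'   sample).
#' @param internal_standard normalizing compound name (default
#'   `"4-Chloro-2-methoxyphenol"`).
#' @param meta optional data.frame with columns `sample`, `class` (and
#'   further columns) keyed by sample id.
#' @return a `compound_table`; see also [binary_compound_table()] for the
#'   qualitative variant.
#' @export
build_compound_table <- function(sample_lists,
                                 internal_standard =
                                   "4-Chloro-2-methoxyphenol",
                                 meta = NULL) {
  samples <- vapply(sample_lists, function(sl)
    if (nrow(sl)) sl$sample[1] else NA_character_, character(1))
  if (any(is.na(samples)) || anyDuplicated(samples))
    stop("each sample list must be nonempty with a unique sample id")
  compounds <- unique(unlist(lapply(sample_lists, function(sl) sl$compound)))
  X <- matrix(0, length(samples), length(compounds))
  for (i in seq_along(sample_lists)) {
    sl <- sample_lists[[i]]
    istd_area <- sl$area[match(internal_standard, sl$compound)]
    if (is.na(istd_area) || istd_area <= 0)
      stop("internal standard '", internal_standard,
           "' missing from sample ", samples[i])
    X[i, match(sl$compound, compounds)] <- sl$area / istd_area
  }
  if (is.null(meta))
    meta <- data.frame(sample = samples, class = NA_character_,
                       stringsAsFactors = FALSE)
  new_compound_table(samples, compounds, X, meta,
                     internal_standard = internal_standard)
}
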