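#' Smooth and floor a chromatogram
#'
#' Per-m/z-channel noise reduction: a centered moving average of odd width
#' `window` (shortened symmetrically at the scan edges, i.e. averaging over
#' the scans actually available), followed by flooring — intensities below
#' `min_intensity` are set to 0. Shape is unchanged.
#'
#' @param m an [intensity_matrix()].
#' @param window odd integer >= 3, in scans.
#' @param min_intensity counts; values below it are zeroed after smoothing.
#' @return an [intensity_matrix()].
#' @export
denoise <- function(m, window = 3L, min_intensity = 0) {
  stopifnot(inherits(m, "intensity_matrix"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  X <- apply(m$intensities, 2, moving_average, window = window)
  X[X < min_intensity] <- 0
  m$intensities <- X
  m
}

# centered moving average with shortened edges; O(n) via cumulative sums
moving_average <- function(x, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect chromatographic components (Biller-Biemann style)
#'
#' Classic coincident-ion-maxima deconvolution: each m/z channel is scanned
#' for local maxima (ties resolved to the earlier scan); a scan at which at
#' least `min_channels` channels place a local maximum within
#' +/- `apex_window` scans is declared a component apex. Runs of qualifying
#' scans are collapsed to the scan with the largest TIC, and apexes closer
#' than `apex_window` scans are merged keeping the larger-TIC apex. Each
#' component's spectrum holds, for every agreeing channel, the channel's
#' apex intensity minus a linear baseline chord between the channel's
#' flanking minima; its area is the baseline-corrected TIC integral
#' ([integrate_area()]). Components below `min_area` are dropped; output is
#' ordered by apex time.
#'
#' @param m an [intensity_matrix()] (raw or denoised).
#' @param apex_window scans (>= 0) within which channel maxima count as
#'   coincident.
#' @param min_channels minimum number of agreeing channels (>= 1).
#' @param min_area minimum baseline-corrected TIC area.
#' @return object of class `component_list`: a list of components, each
#'   with `apex_time`, `apex_scan`, `spectrum` ([mass_spectrum()]), `area`,
#'   and `purity_hint` (fraction of nonzero channels at the apex that
#'   agree).
#' @export
detect_components <- function(m, apex_window = 2L, min_channels = 3L,
                              min_area = 0) {
  stopifnot(inherits(m, "intensity_matrix"))
  apex_window <- as.integer(apex_window)
  min_channels <- as.integer(min_channels)
  if (apex_window < 0L) stop("apex_window must be >= 0")
  if (min_channels < 1L) stop("min_channels must be >= 1")
  X <- m$intensities
  S <- nrow(X)
  total <- rowSums(X)
  # per-channel local maxima: strictly above the left neighbour (so the
  # first scan of a plateau wins) and >= the right neighbour, and nonzero
  left <- rbind(rep(-Inf, ncol(X)), X[-S, , drop = FALSE])
  right <- rbind(X[-1, , drop = FALSE], rep(-Inf, ncol(X)))
  is_max <- (X > left) & (X >= right) & (X > 0)
  # votes per scan: channels with a max within +/- apex_window scans
  max_scan <- which(is_max, arr.ind = TRUE)  # (scan, channel)
  votes <- integer(S)
  if (nrow(max_scan)) {
    for (d in (-apex_window):apex_window) {
      sc <- max_scan[, 1] + d
      ok <- sc >= 1L & sc <= S
      tab <- table(sc[ok])
      votes[as.integer(names(tab))] <- votes[as.integer(names(tab))] +
        as.integer(tab)
    }
  }
  cand <- which(votes >= min_channels)
  if (length(cand) == 0L)
    return(structure(list(), class = "component_list"))
  # collapse runs of qualifying scans (gap <= apex_window) to max-TIC scan
  grp <- cumsum(c(1L, diff(cand) > pmax(apex_window, 1L)))
  apexes <- vapply(split(cand, grp), function(idx)
    idx[which.max(total[idx])], integer(1))
  # merge apexes closer than apex_window scans, keeping the larger TIC
  apexes <- merge_apexes(apexes, total, apex_window)
  comps <- lapply(apexes, function(ap)
    build_component(m, X, is_max, ap, apex_window, total))
  comps <- comps[!vapply(comps, is.null, logical(1))]
  comps <- comps[vapply(comps, function(cc) cc$area >= min_area, logical(1))]
  structure(unname(comps), class = "component_list")
}

merge_apexes <- function(apexes, total, apex_window) {
  apexes <- sort(apexes)
  repeat {
    if (length(apexes) < 2L) return(apexes)
    gaps <- diff(apexes)
    j <- which(gaps < apex_window)
    if (length(j) == 0L) return(apexes)
    j <- j[1]
    drop <- if (total[apexes[j]] >= total[apexes[j + 1]]) j + 1L else j
    apexes <- apexes[-drop]
  }
}

build_component <- function(m, X, is_max, ap, apex_window, total) {
  S <- nrow(X)
  lo <- max(1L, ap - apex_window)
  hi <- min(S, ap + apex_window)
  agree <- which(colSums(is_max[lo:hi, , drop = FALSE]) > 0)
  if (length(agree) == 0L) return(NULL)
  inten <- vapply(agree, function(ch) {
    fl <- find_flanks(X[, ch], ap)
    baseline_at(m$scan_times, X[, ch], fl, ap)
  }, numeric(1))
  keep <- inten > 0
  if (!any(keep)) return(NULL)
  spec <- mass_spectrum(m$mz_axis[agree[keep]], inten[keep])
  nz <- sum(X[ap, ] > 0)
  comp <- list(apex_time = m$scan_times[ap], apex_scan = ap,
               spectrum = spec, area = 0,
               purity_hint = if (nz > 0) min(1, length(agree) / nz) else 0)
  comp$area <- integrate_area(m, comp)
  comp
}

# nearest flanking minima of channel x around scan i (indices)
find_flanks <- function(x, i) {
  n <- length(x)
  l <- i
  while (l > 1L && x[l - 1L] < x[l]) l <- l - 1L
  r <- i
  while (r < n && x[r + 1L] < x[r]) r <- r + 1L
  c(l, r)
}

# apex intensity above the linear chord between flanking minima
baseline_at <- function(times, x, fl, ap) {
  l <- fl[1]; r <- fl[2]
  base <- if (r == l) x[l]
  else x[l] + (x[r] - x[l]) * (times[ap] - times[l]) / (times[r] - times[l])
  max(0, x[ap] - base)
}

#' @export
print.component_list <- function(x, ...) {
  cat("<component_list> ", length(x), " components\n", sep = "")
  if (length(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' @export
as.data.frame.component_list <- function(x, ...) {
  data.frame(apex_time = vapply(x, function(c) c$apex_time, numeric(1)),
             apex_scan = vapply(x, function(c) c$apex_scan, numeric(1)),
             area = vapply(x, function(c) c$area, numeric(1)),
             n_channels = vapply(x, function(c) length(c$spectrum$mz),
                                 numeric(1)),
             purity_hint = vapply(x, function(c) c$purity_hint, numeric(1)))
}

#' Baseline-corrected TIC area of a component
#'
#' Trapezoidal integral of the total ion current between the flanking TIC
#' minima around the component's apex scan, corrected by the linear chord
#' between those minima; clamped at 0. An apex at the matrix edge
#' integrates over the available side only (with a message).
#'
#' @param m the [intensity_matrix()] the component was detected on.
#' @param component a component from [detect_components()] (any list with
#'   an `apex_scan` field).
#' @return non-negative area in counts x minutes.
#' @export
integrate_area <- function(m, component) {
  stopifnot(inherits(m, "intensity_matrix"))
  ap <- component$apex_scan
  S <- length(m$scan_times)
  if (ap < 1L || ap > S) stop("apex_scan outside the matrix")
  total <- rowSums(m$intensities)
  fl <- find_flanks(total, ap)
  if (ap == 1L || ap == S)
    message("component apex at matrix edge (scan ", ap,
            "); integrating one-sided")
  idx <- fl[1]:fl[2]
  if (length(idx) < 2L) return(0)
  t <- m$scan_times[idx]
  y <- total[idx]
  chord <- y[1] + (y[length(y)] - y[1]) *
    (t - t[1]) / (t[length(t)] - t[1])
  max(0, pracma::trapz(t, y - chord))
}
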