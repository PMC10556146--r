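test_that("denoise applies a centered moving average with shortened edges", {
  m <- intensity_matrix(1:5 / 10, c(43, 57),
                        cbind(c(5, 5, 5, 5, 5), c(0, 0, 9, 0, 0)))
  out <- denoise(m, window = 3, min_intensity = 0)
  expect_equal(out$intensities[, 1], rep(5, 5))  # constant fixed point
  expect_equal(out$intensities[, 2], c(0, 3, 3, 3, 0))
  # flooring
  out2 <- denoise(m, window = 3, min_intensity = 4)
  expect_equal(out2$intensities[, 2], rep(0, 5))
  expect_error(denoise(m, window = 4), "odd")
})

test_that("a single planted Gaussian yields one component with the planted spectrum", {
  ch <- five_channels()
  times <- seq(0, 4, by = 0.005)
  pk <- data.frame(rt = 2.0, area = 1e6)
  pk$mz <- list(ch$mz); pk$weights <- list(ch$w)
  m <- plant_peaks(times, 35:110, pk)
  comps <- detect_components(m, apex_window = 2, min_channels = 3,
                             min_area = 100)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$apex_scan, which.min(abs(times - 2.0)))
  got <- spectrum_at(comps[[1]]$spectrum, ch$mz)
  expect_equal(got / max(got), ch$w / max(ch$w), tolerance = 0.01)
  expect_gt(comps[[1]]$purity_hint, 0.99)
})

test_that("two resolved peaks are reported in elution order; empty input is empty", {
  ch <- five_channels()
  times <- seq(0, 4, by = 0.005)
  pk <- data.frame(rt = c(1.5, 1.65), area = c(1e6, 5e5))  # 30 scans apart
  pk$mz <- list(ch$mz, c(50L, 60L, 70L))
  pk$weights <- list(ch$w, c(100, 30, 10))
  m <- plant_peaks(times, 35:110, pk)
  comps <- detect_components(m, apex_window = 3, min_channels = 3)
  expect_length(comps, 2)
  expect_lt(comps[[1]]$apex_time, comps[[2]]$apex_time)
  expect_equal(vapply(comps, function(x) x$apex_time, numeric(1)),
               c(1.5, 1.65), tolerance = 0.01)
  # all-zero matrix
  z <- intensity_matrix(times, 35:110,
                        matrix(0, length(times), length(35:110)))
  expect_length(detect_components(z), 0)
})

test_that("integrated areas match the analytic Gaussian area, baseline removed", {
  ch <- five_channels()
  times <- seq(0, 4, by = 0.005)
  pk <- data.frame(rt = 2.0, area = 1e6)
  pk$mz <- list(ch$mz); pk$weights <- list(ch$w)
  for (b in c(0, 500)) {
    m <- plant_peaks(times, 35:110, pk, baseline = b)
    comps <- detect_components(m, min_area = 1000)
    expect_length(comps, 1)
    expect_equal(comps[[1]]$area, 1e6, tolerance = 0.02)
  }
  # zero-signal region
  z <- intensity_matrix(times, 35:110,
                        matrix(0, length(times), length(35:110)))
  expect_equal(integrate_area(z, list(apex_scan = 100L)), 0)
})

test_that("apex positions are shift-equivariant", {
  ch <- five_channels()
  times <- seq(0, 4, by = 0.005)
  pk <- data.frame(rt = c(1.2, 2.6), area = c(1e6, 8e5))
  pk$mz <- list(ch$mz, ch$mz); pk$weights <- list(ch$w, ch$w)
  m <- plant_peaks(times, 35:110, pk)
  k <- 40L
  # roll all scans forward by k
  rolled <- m$intensities[c((nrow(m$intensities) - k + 1):
                              nrow(m$intensities),
                            1:(nrow(m$intensities) - k)), ]
  m2 <- intensity_matrix(times, m$mz_axis, rolled)
  a1 <- vapply(detect_components(m), function(x) x$apex_scan, numeric(1))
  a2 <- vapply(detect_components(m2), function(x) x$apex_scan, numeric(1))
  expect_equal(sort(a2), sort(a1 + k))
})

test_that("increasing the apex window never increases the component count", {
  set.seed(31)
  ch <- five_channels()
  times <- seq(0, 6, by = 0.005)
  pk <- data.frame(rt = sort(runif(8, 0.5, 5.5)), area = 1e6)
  pk$mz <- rep(list(ch$mz), 8); pk$weights <- rep(list(ch$w), 8)
  m <- plant_peaks(times, 35:110, pk, noise_sd = 20, seed = 31)
  m <- denoise(m, 5, 100)
  n_comp <- vapply(c(1, 2, 4, 8, 16), function(w)
    length(detect_components(m, apex_window = w, min_channels = 3,
                             min_area = 1e4)), numeric(1))
  expect_true(all(diff(n_comp) <= 0))
})

test_that("pure noise yields no detections above a noise-calibrated min_area", {
  set.seed(77)
  times <- seq(0, 2, by = 0.005)
  mz <- 35:80
  # noise-only area distribution: areas of components detected in noise
  noise_areas <- unlist(lapply(1:5, function(i) {
    mn <- plant_peaks(times, mz, data.frame(rt = numeric(0), area = numeric(0),
                                            mz = I(list()),
                                            weights = I(list())),
                      noise_sd = 30)
    mn <- denoise(mn, 5, 0)
    vapply(detect_components(mn, min_area = 0), function(x) x$area,
           numeric(1))
  }))
  min_area <- 5 * quantile(noise_areas, 0.99, names = FALSE)
  for (i in 1:5) {
    mn <- plant_peaks(times, mz, data.frame(rt = numeric(0),
                                            area = numeric(0),
                                            mz = I(list()),
                                            weights = I(list())),
                      noise_sd = 30)
    mn <- denoise(mn, 5, 0)
    expect_length(detect_components(mn, min_area = min_area), 0)
  }
})
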