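test_that("spectral cosine matches hand-computed values", {
  a <- mass_spectrum(c(43, 71), c(100, 50))
  b <- mass_spectrum(c(43, 71), c(50, 100))
  expect_equal(score_ms(a, a), 1.0)
  expect_equal(score_ms(a, b), 0.8)  # 10000 / 12500
  expect_equal(score_ms(a, mass_spectrum(c(91, 105), c(10, 20))), 0)
  expect_equal(score_ms(a, b), score_ms(b, a))
  # scale invariance and proportionality
  b10 <- mass_spectrum(b$mz, b$intensity * 10)
  expect_equal(score_ms(a, b10), score_ms(a, b))
  expect_equal(score_ms(a, mass_spectrum(a$mz, a$intensity * 3.7)), 1.0)
  # all-zero spectra cannot be constructed
  expect_error(mass_spectrum(43, 0), "nonzero")
})

test_that("cosine equals a dense-vector oracle on random sparse spectra", {
  dense_cosine <- function(a, b) {
    va <- spectrum_to_vector(a, 500)
    vb <- spectrum_to_vector(b, 500)
    sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  }
  set.seed(99)
  for (i in 1:100) {
    na <- sample(2:20, 1); nb <- sample(2:20, 1)
    a <- mass_spectrum(sample(500, na), runif(na, 1, 100))
    b <- mass_spectrum(sample(500, nb), runif(nb, 1, 100))
    expect_equal(score_ms(a, b), dense_cosine(a, b), tolerance = 1e-12)
  }
})

test_that("combined score follows the RI-offset formula and the 30-unit window", {
  expect_equal(score_ms_ri(1, 1500, 1500), 1.0)
  expect_equal(score_ms_ri(0.9, 1000, 1010),
               1 - ((1 - 0.9) + 10 / 1010) / 2)
  expect_equal(score_ms_ri(0.9, 1000, 1010), 0.9450495, tolerance = 1e-7)
  expect_equal(score_ms_ri(1, 1031, 1000), 0)   # just outside the window
  expect_equal(score_ms_ri(1, 1030, 1000), 1 - (30 / 1000) / 2)  # boundary in
  expect_equal(score_ms_ri(0.6, 1200, 1200), (1 + 0.6) / 2)
  expect_error(score_ms_ri(1.2, 1000, 1000), "\\[0, 1\\]")
  expect_error(score_ms_ri(0.5, 1000, -5), "positive")
})

test_that("combined score is monotone in |RI delta| and bounded in [0,1]", {
  s <- 0.85
  deltas <- seq(0, 40, by = 0.5)
  v <- score_ms_ri(s, 1000 + deltas, 1000)
  expect_true(all(diff(v) <= 0))
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(v[1], (1 + s) / 2)
  expect_true(all(v[deltas > 30] == 0))
})

test_that("match_component ranks by combined score and honours the threshold", {
  lib <- list(
    library_entry("target", 1200, mass_spectrum(c(43, 57, 71),
                                                c(100, 40, 20))),
    library_entry("isomer", 1204, mass_spectrum(c(43, 57, 71),
                                                c(100, 42, 22))),
    library_entry("far", 1400, mass_spectrum(c(43, 57, 71),
                                             c(100, 40, 20))))
  comp <- list(spectrum = mass_spectrum(c(43, 57, 71), c(100, 40, 20)))
  mm <- match_component(comp, 1200, lib)
  expect_equal(mm$name[1], "target")
  expect_equal(mm$score_ms_ri[1], 1.0)
  expect_equal(mm$rank, seq_len(nrow(mm)))
  # isomer pair: both pass, ranked 1 and 2
  expect_equal(mm$name[2], "isomer")
  expect_gt(mm$score_ms_ri[2], 0.9)
  expect_false("far" %in% mm$name)  # outside the 30-unit window
  # nothing within the RI window -> empty
  mm2 <- match_component(comp, 1600, lib)
  expect_equal(nrow(mm2), 0)
})

test_that("sample lists keep one occurrence per compound, largest area", {
  lib <- list(library_entry("3-Methylbutanol", 1209,
                            mass_spectrum(c(55, 70), c(100, 30))))
  mk <- function(rt, area)
    list(apex_time = rt, apex_scan = 1L, area = area,
         spectrum = mass_spectrum(c(55, 70), c(100, 30)))
  comps <- structure(list(mk(10, 500), mk(10.4, 80)),
                     class = "component_list")
  sl <- suppressWarnings(build_sample_list(comps, c(1209, 1212), lib,
                                           sample_id = "w1"))
  expect_equal(nrow(sl), 1)
  expect_equal(sl$area, 500)
  expect_equal(sl$compound, "3-Methylbutanol")
  # missing internal standards warn
  expect_warning(build_sample_list(comps, c(1209, 1212), lib),
                 "internal standard")
  # component with no passing match is excluded
  far <- structure(list(mk(10, 500)), class = "component_list")
  sl2 <- suppressWarnings(build_sample_list(far, 1500, lib))
  expect_equal(nrow(sl2), 0)
})

test_that("blank subtraction removes shared compounds below ratio 3, strictly", {
  sample <- data.frame(sample = "s", compound = c("a", "b", "c", "d"),
                       area = c(250, 300, 50, 40))
  blank <- data.frame(sample = "blank", compound = c("a", "b", "d", "e"),
                      area = c(100, 100, 0, 10))
  expect_message(subtract_blank(sample, blank), "kept")
  out <- suppressMessages(subtract_blank(sample, blank))
  expect_false("a" %in% out$compound)        # 2.5 < 3 removed
  expect_true("b" %in% out$compound)         # 3.0 kept (strict rule)
  expect_true("c" %in% out$compound)         # absent from blank
  expect_true("d" %in% out$compound)         # blank area 0 -> +Inf
  expect_false("e" %in% out$compound)        # blank-only ignored
})

test_that("compound tables normalize to the internal standard", {
  tab <- new_ct_fixture()
  expect_equal(dim(tab$rel_area), c(2L, 3L))
  expect_equal(unname(tab$rel_area[, "4-Chloro-2-methoxyphenol"]), c(1, 1))
  expect_equal(unname(tab$rel_area["S1", "Ethyl hexanoate"]), 52.34567 / 100)
  expect_equal(unname(tab$rel_area["S2", "Vanillin"]), 0)  # structural zero
  # binary variant
  b <- binary_compound_table(tab)
  expect_true(all(b$rel_area %in% c(0, 1)))
  expect_equal(unname(b$rel_area["S2", "Vanillin"]), 0)
  expect_equal(unname(b$rel_area["S1", "Vanillin"]), 1)
  # missing internal standard
  sl <- data.frame(sample = "S3", compound = "Vanillin", area = 5)
  expect_error(build_compound_table(list(sl)), "internal standard")
})
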