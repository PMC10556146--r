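test_that("the model-whisky composition fixture matches the printed table", {
  t1 <- load_table1()
  expect_equal(nrow(t1$model1), 27)
  expect_equal(nrow(t1$model2), 26)
  expect_equal(t1$model1$concentration[t1$model1$compound == "Furfural"],
               3.07)
  expect_equal(t1$model2$concentration[t1$model2$compound == "Furfural"],
               1.53)
  # cis/trans whisky lactone expanded into two stereoisomer entries
  expect_true(all(c("cis-Whisky lactone", "trans-Whisky lactone") %in%
                    t1$model1$compound))
  # internal standards as printed
  istd <- internal_standards_spec()
  expect_equal(istd$concentration[istd$compound ==
                                    "4-Chloro-2-methoxyphenol"], 48.2)
  expect_equal(istd$concentration[istd$compound == "n-Undecane"], 43.25)
})

test_that("library generation is deterministic and sized as requested", {
  t1 <- load_table1()
  l1 <- make_library(t1$model1, decoys = 20, seed = 33)
  l2 <- make_library(t1$model1, decoys = 20, seed = 33)
  expect_equal(l1, l2)
  # composition + 2 internal standards + phenol contaminant + decoys
  expect_length(l1, 27 + 2 + 1 + 20)
  l0 <- make_library(t1$model1, decoys = 0, seed = 33)
  expect_length(l0, 27 + 2 + 1)
  # isomer stress-pair: RI within 5 and cosine >= 0.95
  nm <- vapply(l1, function(e) e$name, character(1))
  iso <- l1[[grep("-iso$", nm)]]
  partner <- l1[[grep("-iso$", nm) - 1L]]
  expect_lte(abs(iso$ri - partner$ri), 5)
  expect_gte(score_ms(iso$spectrum, partner$spectrum), 0.95)
})

test_that("noise-free runs conserve planted areas and place peaks exactly", {
  cfg <- simulation_config(noise_sd = 0, baseline = 0, rt_jitter_sd = 0,
                           seed = 44)
  lib <- make_library("Ethyl octanoate", seed = 44)
  run <- simulate_run(data.frame(compound = "Ethyl octanoate",
                                 concentration = 2), lib, cfg = cfg)
  # TIC integral equals the planted area within 1%
  total <- rowSums(run$matrix$intensities)
  expect_equal(pracma::trapz(run$matrix$scan_times, total),
               sum(run$truth$area), tolerance = 0.01)
  # detection lands within one scan of the planted position
  comps <- detect_components(run$matrix, min_area = 100)
  expect_length(comps, 1)
  planted_scan <- which.min(abs(run$matrix$scan_times - run$truth$rt))
  expect_lte(abs(comps[[1]]$apex_scan - planted_scan), 1)
  # missing library compound is named in the error
  expect_error(simulate_run(data.frame(compound = "Unobtainium",
                                       concentration = 1), lib, cfg = cfg),
               "Unobtainium")
})

test_that("blank runs contain only contaminants and internal standards", {
  t1 <- load_table1()
  lib <- make_library(t1$model1, seed = 55)
  cfg <- simulation_config(seed = 55)
  blank <- simulate_blank(lib, cfg)
  expect_true(blank$matrix$is_blank)
  expect_setequal(blank$truth$compound,
                  c("Furfural", "Phenol", "n-Undecane",
                    "4-Chloro-2-methoxyphenol"))
})

test_that("simulated panels are deterministic and obey the max-5 rule", {
  p1 <- simulate_panel(seed = 66)
  p2 <- simulate_panel(seed = 66)
  expect_equal(p1$records, p2$records)
  checked <- p1$records[p1$records$intensity >= 1, ]
  k <- table(paste(checked$panellist, checked$sample))
  expect_lte(max(k), 5)
  expect_true(all(p1$records$intensity %in% 0:3))
  # default design: 11 panellists, 32 sample presentations
  expect_length(unique(p1$records$panellist), 11)
  expect_equal(nrow(p1$sample_meta), 32)
  expect_error(simulate_panel(effects = c(nonsense = 1), seed = 1),
               "unknown attributes")
})

test_that("planted sensory class effects surface as top delta predictors", {
  pan <- simulate_panel(effects = c(caramel = 2), seed = 12)
  fm <- sensory_feature_matrix(aggregate_rata(pan))
  expect_equal(dim(fm$X), c(16L, 34L))  # 17 attributes x 2 ABV levels
  r <- run_protocol(fm, reps = 300, seed = 12)
  expect_true(grepl("^caramel", r$delta$feature[1]))
})

test_that("simulated compound tables plant the requested signal structure", {
  sim <- simulate_compound_table(seed = 77)
  expect_equal(dim(sim$table$rel_area), c(16L, 200L))
  expect_length(sim$informative, 4)
  expect_true(all(sim$table$rel_area >= 0))
  # planted compounds separate the classes by ~2 pooled SDs
  X <- sim$table$rel_area
  y <- sim$feature_matrix$y
  for (j in sim$informative) {
    d <- abs(mean(X[y == "American", j]) - mean(X[y == "Scotch", j]))
    sp <- sqrt((8 * var(X[y == "Scotch", j]) + 6 * var(X[y == "American", j]))
               / 14)
    expect_gt(d / sp, 0.8)
  }
  expect_equal(sim$table$rel_area,
               simulate_compound_table(seed = 77)$table$rel_area)
})
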