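test_that("the Fisher discriminant separates well-separated clouds", {
  set.seed(1)
  X <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 6), 10, 2))
  y <- rep(c("A", "B"), each = 10)
  fit <- fit_lda(X, y)
  expect_equal(mean(predict(fit, X) == y), 1)
  expect_error(fit_lda(X, rep("A", 20)), "2 classes")
  expect_error(fit_lda(X[c(1, 11:20), ], y[c(1, 11:20)]), ">= 2")
})

test_that("ridge regularization makes duplicated features harmless", {
  set.seed(2)
  X <- rbind(matrix(rnorm(24, 0), 8, 3), matrix(rnorm(24, 3), 8, 3))
  y <- rep(c("A", "B"), each = 8)
  Xdup <- cbind(X, X)  # perfectly collinear
  fit0 <- fit_lda(X, y)
  fit1 <- fit_lda(Xdup, y)
  expect_gt(fit1$lambda, 0)
  expect_equal(as.character(predict(fit1, Xdup)),
               as.character(predict(fit0, X)))
})

test_that("hand-rolled LDA predictions agree with MASS::lda on full-rank data", {
  skip_if_not_installed("MASS")
  set.seed(3)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 1.2), 20, 2))
  colnames(X) <- c("f1", "f2")
  y <- factor(rep(c("A", "B"), each = 20))
  mine <- predict(fit_lda(X, y), X)
  ref <- predict(MASS::lda(X, grouping = y), X)$class
  expect_equal(as.character(mine), as.character(ref))
})

test_that("all 560 training subsets of 13 from 16 are enumerable", {
  subsets <- enumerate_train_subsets(16, 13)
  expect_equal(ncol(subsets), choose(16, 13))
  expect_equal(ncol(subsets), 560)
  expect_equal(anyDuplicated(apply(subsets, 2, paste, collapse = ",")), 0L)
})

test_that("the protocol is deterministic under a seed and internally consistent", {
  sim <- simulate_compound_table(seed = 4)
  fm <- sim$feature_matrix
  r1 <- run_protocol(fm, reps = 300, seed = 10)
  r2 <- run_protocol(fm, reps = 300, seed = 10)
  expect_equal(r1$per_rep, r2$per_rep)
  expect_equal(r1$subset_log, r2$subset_log)
  expect_equal(r1$delta, r2$delta)
  # perfect repetitions are a subset of correct classifications
  expect_lte(r1$perfect_rate, r1$mean_test)
  # test accuracies quantized to thirds
  expect_true(all(r1$per_rep$test_accuracy %in% c(0, 1 / 3, 2 / 3, 1)))
  expect_error(run_protocol(fm, reps = 10, n_train = 10, seed = 1),
               "must equal")
})

test_that("a perfectly separating feature yields a 100% perfect rate", {
  set.seed(5)
  X <- cbind(sep = rep(c(0, 10), c(9, 7)) + rnorm(16, 0, 0.1),
             noise = rnorm(16))
  fm <- feature_matrix(X, rep(c("Scotch", "American"), c(9, 7)))
  r <- run_protocol(fm, reps = 200, seed = 6)
  expect_equal(r$perfect_rate, 100)
  expect_equal(r$delta$feature[1], "sep")
})

test_that("PCA keeping full rank reproduces the no-PCA analysis", {
  set.seed(7)
  X <- rbind(matrix(rnorm(36, 0), 9, 4), matrix(rnorm(28, 2), 7, 4))
  fm <- feature_matrix(X, rep(c("S", "A"), c(9, 7)),
                       paste0("f", 1:4))
  r0 <- run_protocol(fm, reps = 150, seed = 8)
  r4 <- run_protocol(fm, reps = 150, pca_components = 4, seed = 8)
  expect_equal(r4$per_rep$test_accuracy, r0$per_rep$test_accuracy)
  expect_equal(r4$subset_log, r0$subset_log)
})

test_that("delta predictors find planted signal and are scale-invariant", {
  sim <- simulate_compound_table(n_compounds = 40, n_informative = 1,
                                 effect = 3, seed = 9)
  r <- run_protocol(sim$feature_matrix, reps = 300, seed = 11)
  expect_equal(r$delta$feature[1], sim$informative)
  # a feature identical across classes has influence ~ 0
  X <- sim$feature_matrix$X
  X <- cbind(X, constant = 5)
  fm2 <- feature_matrix(X, sim$feature_matrix$y)
  r2 <- run_protocol(fm2, reps = 150, seed = 12)
  expect_lt(r2$delta$influence[r2$delta$feature == "constant"], 1e-8)
  # rescaling a feature by 10x leaves its influence unchanged: exact in
  # the full-rank (ridge-free) case
  j <- which(colnames(sim$feature_matrix$X) == sim$informative)
  keep <- c(j, setdiff(seq_len(6), j)[1:5])
  Xs <- sim$feature_matrix$X[, keep]
  X3 <- Xs
  X3[, 1] <- X3[, 1] * 10
  r3 <- run_protocol(feature_matrix(X3, sim$feature_matrix$y),
                     reps = 150, seed = 13)
  r3b <- run_protocol(feature_matrix(Xs, sim$feature_matrix$y),
                      reps = 150, seed = 13)
  expect_equal(r3$delta$influence[r3$delta$feature == sim$informative],
               r3b$delta$influence[r3b$delta$feature == sim$informative],
               tolerance = 1e-9)
  # and approximate under the ridge (high-dimensional) regime
  X4 <- sim$feature_matrix$X
  X4[, j] <- X4[, j] * 10
  r4 <- run_protocol(feature_matrix(X4, sim$feature_matrix$y),
                     reps = 150, seed = 13)
  r4b <- run_protocol(sim$feature_matrix, reps = 150, seed = 13)
  expect_equal(r4$delta$influence[r4$delta$feature == sim$informative],
               r4b$delta$influence[r4b$delta$feature == sim$informative],
               tolerance = 0.05)
})

test_that("training draws missing a class are redrawn", {
  set.seed(14)
  X <- cbind(rnorm(16), rnorm(16))
  y <- rep(c("A", "B"), c(14, 2))
  fm <- feature_matrix(X, y)
  r <- run_protocol(fm, reps = 100, seed = 15)
  expect_gt(r$redraws, 0)
  # every logged training set keeps both class-B members
  expect_true(all(apply(r$subset_log, 1, function(tr) all(c(15, 16) %in% tr))))
})
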