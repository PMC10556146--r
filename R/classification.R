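#' Construct a feature matrix for two-class classification
#'
#' One row per physical sample (e.g. per whisky, concatenating the 20% and
#' 40% ABV sensory means, and/or relative peak areas), a two-level class
#' label per row.
#'
#' @param X numeric samples x features matrix (no missing values).
#' @param y class labels, exactly 2 levels, >= 2 samples each.
#' @param feature_names optional; defaults to `colnames(X)`.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(X, y, feature_names = colnames(X)) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X must have no missing values")
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("y must have exactly 2 classes")
  if (any(table(y) < 2L)) stop("need >= 2 samples per class")
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  if (is.null(feature_names))
    feature_names <- paste0("f", seq_len(ncol(X)))
  colnames(X) <- feature_names
  structure(list(X = X, y = y, feature_names = feature_names),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$X), " samples x ", ncol(x$X),
      " features; classes: ",
      paste(sprintf("%s (%d)", levels(x$y), table(x$y)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Fisher linear discriminant with ridge fallback
#'
#' Two-class Fisher discriminant `w = Sigma_pooled^-1 (mu_A - mu_B)`, with
#' a ridge term `lambda I` added when the pooled within-class covariance is
#' singular (the usual situation with more features than training samples);
#' `lambda = ridge * trace(Sigma) / p` by default. The decision threshold
#' sits at the midpoint of the projected class means.
#'
#' @param X numeric training matrix (samples x features).
#' @param y two-level class labels, both present, >= 2 samples each.
#' @param ridge relative ridge coefficient (default 1e-6).
#' @return object of class `fisher_lda` with elements `w`, `threshold`,
#'   `levels` (first level predicted when the projection exceeds the
#'   threshold), `means`, `lambda`.
#' @export
fit_lda <- function(X, y, ridge = 1e-6) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2L) stop("fit_lda needs exactly 2 classes in y")
  if (any(table(y) < 2L)) stop("each class needs >= 2 training samples")
  lv <- levels(y)
  Xa <- X[y == lv[1], , drop = FALSE]
  Xb <- X[y == lv[2], , drop = FALSE]
  mu_a <- colMeans(Xa)
  mu_b <- colMeans(Xb)
  p <- ncol(X)
  Sp <- ((nrow(Xa) - 1) * stats::cov(Xa) +
         (nrow(Xb) - 1) * stats::cov(Xb)) / (nrow(X) - 2)
  lambda <- 0
  ch <- tryCatch(chol(Sp), error = function(e) NULL)
  if (is.null(ch)) {
    lambda <- ridge * sum(diag(Sp)) / p
    if (lambda <= 0) lambda <- ridge
    ch <- chol(Sp + diag(lambda, p))
  }
  w <- backsolve(ch, forwardsolve(t(ch), mu_a - mu_b))
  thr <- sum(w * (mu_a + mu_b)) / 2
  structure(list(w = as.numeric(w), threshold = thr, levels = lv,
                 means = rbind(mu_a, mu_b), lambda = lambda),
            class = "fisher_lda")
}

#' @export
print.fisher_lda <- function(x, ...) {
  cat("<fisher_lda> ", length(x$w), " features; classes ",
      paste(x$levels, collapse = " vs "),
      if (x$lambda > 0) sprintf("; ridge lambda %.3g", x$lambda),
      "\n", sep = "")
  invisible(x)
}

#' @export
coef.fisher_lda <- function(object, ...) {
  stats::setNames(object$w, colnames(object$means))
}

#' @export
predict.fisher_lda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  proj <- drop(newdata %*% object$w)
  factor(ifelse(proj > object$threshold, object$levels[1], object$levels[2]),
         levels = object$levels)
}

#' Enumerate all training subsets of a repeated-subsampling design
#'
#' All distinct training index sets of size `n_train` from `n` samples:
#' `choose(n, n_train)` sets — 560 for the 13-of-16 design.
#'
#' @param n total number of samples.
#' @param n_train training-set size.
#' @return integer matrix, one column per subset (as [utils::combn()]).
#' @export
enumerate_train_subsets <- function(n, n_train) {
  utils::combn(n, n_train)
}

#' Repeated-subsampling LDA classification protocol
#'
#' Each repetition draws a uniform random test set of `n_test` samples
#' (train = the rest; redrawn, with a count kept, if a class is absent
#' from the training draw). Optionally a PCA (centering only) is fitted on
#' the training samples and both sets are projected onto the leading
#' `pca_components` components. A stratified `folds`-fold cross-validation
#' accuracy is recorded on the training set, then the final discriminant is
#' fitted on all training samples and scored on the test set. The headline
#' `perfect_rate` is the percentage of repetitions whose test accuracy is
#' 100%; `mean_test` and `mean_cv` are the average test and cross-validated
#' training accuracies.
#'
#' @param fm a [feature_matrix()].
#' @param reps repetitions (default 5000).
#' @param n_train,n_test split sizes; must sum to the number of samples
#'   (defaults 13 and 3 for a 16-sample set, giving 560 distinct splits).
#' @param folds cross-validation folds (default 5).
#' @param pca_components optional integer; PCA-reduce before LDA.
#' @param seed RNG seed (mandatory: the subset draws are the only source
#'   of randomness and must be reproducible).
#' @param ridge passed to [fit_lda()].
#' @return object of class `lda_protocol`: `perfect_rate`, `mean_test`,
#'   `mean_cv` (percent), `per_rep` (data.frame of per-repetition test and
#'   CV accuracies), `delta` (per-feature influence, mean 1, sorted;
#'   see [delta_predictors()]), `subset_log` (reps x n_train matrix of
#'   drawn training indices), `n_distinct_subsets`, `redraws`, `call`
#'   parameters.
#' @export
run_protocol <- function(fm, reps = 5000, n_train = 13, n_test = 3,
                         folds = 5, pca_components = NULL, seed,
                         ridge = 1e-6) {
  stopifnot(inherits(fm, "feature_matrix"))
  n <- nrow(fm$X)
  if (n_train + n_test != n)
    stop("n_train + n_test must equal the number of samples (", n, ")")
  if (reps < 1) stop("reps must be >= 1")
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  X <- fm$X
  y <- fm$y
  p <- ncol(X)
  test_acc <- numeric(reps)
  cv_acc <- numeric(reps)
  subset_log <- matrix(0L, reps, n_train)
  W <- matrix(0, reps, p)
  redraws <- 0L
  for (r in seq_len(reps)) {
    repeat {
      test_idx <- sample.int(n, n_test)
      train_idx <- setdiff(seq_len(n), test_idx)
      if (nlevels(droplevels(y[train_idx])) == 2L &&
          all(table(y[train_idx]) >= 2L)) break
      redraws <- redraws + 1L
    }
    subset_log[r, ] <- sort(train_idx)
    Xtr <- X[train_idx, , drop = FALSE]
    Xte <- X[test_idx, , drop = FALSE]
    ytr <- y[train_idx]
    rot <- NULL
    if (!is.null(pca_components)) {
      pc <- stats::prcomp(Xtr, center = TRUE, scale. = FALSE)
      k <- min(pca_components, ncol(pc$rotation))
      rot <- pc$rotation[, seq_len(k), drop = FALSE]
      ctr <- pc$center
      Xtr <- sweep(Xtr, 2, ctr) %*% rot
      Xte <- sweep(Xte, 2, ctr) %*% rot
    }
    cv_acc[r] <- cv_accuracy(Xtr, ytr, folds, ridge)
    fit <- fit_lda(Xtr, ytr, ridge = ridge)
    test_acc[r] <- mean(predict(fit, Xte) == y[test_idx])
    W[r, ] <- if (is.null(rot)) fit$w else drop(rot %*% fit$w)
  }
  delta <- delta_predictors(W, X, y, feature_names = fm$feature_names)
  key <- apply(subset_log, 1, paste, collapse = ",")
  structure(list(reps = reps,
                 perfect_rate = 100 * mean(test_acc == 1),
                 mean_test = 100 * mean(test_acc),
                 mean_cv = 100 * mean(cv_acc),
                 per_rep = data.frame(test_accuracy = test_acc,
                                      cv_accuracy = cv_acc),
                 delta = delta,
                 subset_log = subset_log,
                 n_distinct_subsets = length(unique(key)),
                 redraws = redraws,
                 n_train = n_train, n_test = n_test, folds = folds,
                 pca_components = pca_components, seed = seed),
            class = "lda_protocol")
}

# stratified k-fold CV accuracy of the ridge-LDA on one training set
cv_accuracy <- function(X, y, folds, ridge) {
  n <- nrow(X)
  fold_id <- integer(n)
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  correct <- logical(n)
  for (f in seq_len(folds)) {
    hold <- which(fold_id == f)
    if (length(hold) == 0L) next
    keep <- setdiff(seq_len(n), hold)
    if (nlevels(droplevels(y[keep])) < 2L || any(table(y[keep]) < 2L)) {
      correct[hold] <- FALSE
      next
    }
    fit <- fit_lda(X[keep, , drop = FALSE], y[keep], ridge = ridge)
    correct[hold] <- predict(fit, X[hold, , drop = FALSE]) == y[hold]
  }
  mean(correct)
}

#' Per-feature influence of the fitted discriminants
#'
#' For every repetition's discriminant weights, the influence of feature j
#' is `|w_j| * sd_j`, where `sd_j` is the pooled within-class standard
#' deviation of the feature over the full data (so the measure is
#' invariant to feature rescaling). Influences are averaged over
#' repetitions and reported on a scale with mean 1, sorted descending;
#' values above `flag_threshold` mark top predictors.
#'
#' @param W reps x features matrix of discriminant weights (in the
#'   original feature space).
#' @param X full samples x features matrix.
#' @param y class labels.
#' @param feature_names feature names.
#' @param flag_threshold flag level (default 2).
#' @return data.frame with columns `feature`, `influence`, `flagged`,
#'   sorted by descending influence.
#' @export
delta_predictors <- function(W, X, y, feature_names = colnames(X),
                             flag_threshold = 2) {
  W <- as.matrix(W)
  X <- as.matrix(X)
  y <- factor(y)
  sd_pooled <- sqrt(apply(X, 2, function(col) {
    v <- tapply(col, y, stats::var)
    n <- tapply(col, y, length)
    sum((n - 1) * v) / (sum(n) - length(v))
  }))
  sd_pooled[!is.finite(sd_pooled)] <- 0
  infl <- colMeans(abs(W)) * sd_pooled
  if (mean(infl) > 0) infl <- infl / mean(infl)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_along(infl))
  out <- data.frame(feature = feature_names, influence = infl,
                    flagged = infl > flag_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$influence), ]
  rownames(out) <- NULL
  out
}

#' @export
print.lda_protocol <- function(x, ...) {
  cat("<lda_protocol> ", x$reps, " repetitions, ", x$n_train, "/",
      x$n_test, " split, ", x$folds, "-fold CV",
      if (!is.null(x$pca_components))
        paste0(", PCA ", x$pca_components, " components"), "\n", sep = "")
  cat(sprintf("  perfect test repetitions: %.2f%%\n", x$perfect_rate))
  cat(sprintf("  mean test accuracy:       %.2f%%\n", x$mean_test))
  cat(sprintf("  mean CV accuracy:         %.2f%%\n", x$mean_cv))
  cat("  distinct training subsets realized: ", x$n_distinct_subsets,
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.lda_protocol <- function(object, ...) {
  print(object)
  cat("\nTop predictors (influence scale: mean = 1):\n")
  print(utils::head(object$delta, 10), row.names = FALSE)
  invisible(object)
}

#' @export
coef.lda_protocol <- function(object, ...) {
  stats::setNames(object$delta$influence, object$delta$feature)
}

#' @export
plot.lda_protocol <- function(x, n = 15, ...) {
  d <- utils::head(x$delta, n)
  graphics::barplot(rev(d$influence), names.arg = rev(d$feature),
                    horiz = TRUE, las = 1, xlab = "delta predictor",
                    main = "Feature influence on class separation", ...)
  graphics::abline(v = 2, lty = 2)
  invisible(x)
}
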