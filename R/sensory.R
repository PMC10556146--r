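#' Aggregate a RATA dataset into sample x attribute matrices
#'
#' Splits the raw records into intensity (RATA) and qualitative (CATA)
#' summaries: `rata_mean[s, a]` is the sum of ratings divided by the
#' number of panellists (unchecked = 0), `cata_prop[s, a]` the fraction of
#' panellists who checked the attribute. `"other"` records are excluded.
#'
#' @param r a [rata_dataset()].
#' @return object of class `sensory_matrix` with fields `rata_mean`,
#'   `cata_prop` (samples x attributes), `n_panellists`, `sample_meta`.
#' @export
aggregate_rata <- function(r) {
  stopifnot(inherits(r, "rata_dataset"))
  samples <- r$sample_meta$sample
  attrs <- r$attributes
  panellists <- unique(r$records$panellist)
  np <- length(panellists)
  rec <- r$records[r$records$attribute != "other", ]
  si <- match(rec$sample, samples)
  ai <- match(rec$attribute, attrs)
  sums <- matrix(0, length(samples), length(attrs),
                 dimnames = list(samples, attrs))
  counts <- sums
  for (k in seq_len(nrow(rec))) {
    sums[si[k], ai[k]] <- sums[si[k], ai[k]] + rec$intensity[k]
    counts[si[k], ai[k]] <- counts[si[k], ai[k]] + (rec$intensity[k] >= 1L)
  }
  structure(list(rata_mean = sums / np, cata_prop = counts / np,
                 n_panellists = np, sample_meta = r$sample_meta),
            class = "sensory_matrix")
}

#' @export
print.sensory_matrix <- function(x, ...) {
  cat("<sensory_matrix> ", nrow(x$rata_mean), " samples x ",
      ncol(x$rata_mean), " attributes, ", x$n_panellists, " panellists\n",
      sep = "")
  invisible(x)
}

#' Cochran's Q test on a binary block design
#'
#' Q over `k` treatments (samples) with blocks (panellists):
#' `Q = k (k-1) sum_j (C_j - N/k)^2 / (k N - sum_i R_i^2)` with column
#' totals `C_j`, row totals `R_i`, grand total `N`; p-value from the
#' chi-square distribution with `k - 1` degrees of freedom. Degenerate
#' inputs (no variation: every block all-0 or all-1) return Q = 0, p = 1.
#'
#' @param mat binary blocks x treatments matrix.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
cochran_q <- function(mat) {
  mat <- as.matrix(mat)
  if (!all(mat %in% c(0, 1))) stop("cochran_q needs a binary matrix")
  k <- ncol(mat)
  Cj <- colSums(mat)
  Ri <- rowSums(mat)
  N <- sum(mat)
  denom <- k * N - sum(Ri^2)
  if (denom <= 0)
    return(list(statistic = 0, df = k - 1L, p.value = 1))
  Q <- k * (k - 1) * sum((Cj - N / k)^2) / denom
  list(statistic = Q, df = k - 1L,
       p.value = stats::pchisq(Q, k - 1, lower.tail = FALSE))
}

#' Per-attribute significance of CATA citation patterns
#'
#' For each scored attribute, the checked/unchecked indicator is laid out
#' as a panellist x sample binary matrix and tested with [cochran_q()]
#' (blocks = panellists, treatments = samples). Attributes never or always
#' checked are degenerate: p = 1, not significant.
#'
#' @param r a [rata_dataset()] with a complete panellist x sample design.
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `attribute`, `Q`, `df`, `p`,
#'   `significant`.
#' @export
cata_significance <- function(r, alpha = 0.05) {
  stopifnot(inherits(r, "rata_dataset"))
  samples <- r$sample_meta$sample
  panellists <- unique(r$records$panellist)
  if (length(samples) < 2L || length(panellists) < 2L)
    stop("need >= 2 samples and >= 2 panellists")
  res <- lapply(r$attributes, function(a) {
    rec <- r$records[r$records$attribute == a & r$records$intensity >= 1L, ]
    mat <- matrix(0, length(panellists), length(samples))
    if (nrow(rec))
      mat[cbind(match(rec$panellist, panellists),
                match(rec$sample, samples))] <- 1
    q <- cochran_q(mat)
    data.frame(attribute = a, Q = q$statistic, df = q$df, p = q$p.value,
               significant = q$p.value < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Principal coordinate analysis (classical MDS)
#'
#' Classical scaling of the Euclidean distance matrix of the input rows
#' (via [stats::cmdscale()]). For a Euclidean distance the coordinates
#' reproduce the pairwise distances exactly when all positive eigenvalues
#' are kept; negative eigenvalues are dropped (with a message) and the
#' explained proportions are taken over the positive ones.
#'
#' @param mat numeric samples x attributes matrix (e.g. `cata_prop` from
#'   [aggregate_rata()]).
#' @param k number of axes to return; default all positive-eigenvalue axes.
#' @return object of class `pcoa_result` with `coordinates` (samples x
#'   axes) and `explained` (non-increasing, sums to <= 1).
#' @export
pcoa <- function(mat, k = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3L) stop("need >= 3 samples")
  d <- stats::dist(mat)
  n <- nrow(mat)
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  tol <- max(abs(eig)) * 1e-8
  if (any(eig < -tol))
    message("dropping ", sum(eig < -tol), " negative eigenvalue(s)")
  pos <- which(eig > tol)
  if (is.null(k)) k <- length(pos)
  k <- min(k, length(pos))
  coords <- fit$points[, pos[seq_len(k)], drop = FALSE]
  rownames(coords) <- rownames(mat)
  colnames(coords) <- paste0("PCo", seq_len(k))
  structure(list(coordinates = coords,
                 explained = eig[pos[seq_len(k)]] / sum(eig[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("<pcoa_result> ", nrow(x$coordinates), " samples, ",
      ncol(x$coordinates), " axes; PCo1+2 explain ",
      sprintf("%.1f%%", 100 * sum(x$explained[seq_len(
        min(2, length(x$explained)))])), " of distance\n", sep = "")
  invisible(x)
}
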