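# in-code fixture builders shared across test files

# chromatogram with Gaussian peaks planted on selected channels
# peaks: data.frame(rt, area, mz (list of ints), weights (list))
plant_peaks <- function(times, mz_axis, peaks, baseline = 0, noise_sd = 0,
                        sigma = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(baseline, length(times), length(mz_axis))
  for (i in seq_len(nrow(peaks))) {
    amp_tot <- peaks$area[i] / (sigma * sqrt(2 * pi))
    w <- peaks$weights[[i]] / sum(peaks$weights[[i]])
    g <- exp(-(times - peaks$rt[i])^2 / (2 * sigma^2))
    ch <- match(peaks$mz[[i]], mz_axis)
    X[, ch] <- X[, ch] + outer(g, amp_tot * w)
  }
  if (noise_sd > 0)
    X <- X + matrix(rnorm(length(X), 0, noise_sd), nrow(X), ncol(X))
  X[X < 0] <- 0
  intensity_matrix(times, mz_axis, X, "fixture")
}

# five-channel test spectrum weights
five_channels <- function() list(mz = c(43L, 57L, 71L, 85L, 99L),
                                 w = c(100, 80, 60, 40, 20))

# minimal two-entry MSP text fixture
write_tiny_msp <- function(path) {
  writeLines(c(
    "Name: Ethyl hexanoate",
    "CAS: 123-66-0",
    "RI: 1233",
    "Num Peaks: 2",
    "43 100 71 50",
    "",
    "Name: Furfural",
    "RI: 1461",
    "95 100",
    "96 40"
  ), path)
  path
}

# small two-class RATA record set within the max-5 rule
tiny_rata <- function() {
  rec <- expand.grid(panellist = c("P1", "P2", "P3"),
                     sample = c("S1", "A1"),
                     stringsAsFactors = FALSE)
  rec <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i)
    data.frame(rec[i, ], attribute = c("fruity", "smoky"),
               intensity = c(2L, 1L), row.names = NULL)))
  meta <- data.frame(sample = c("S1", "A1"),
                     class = c("Scotch", "American"), abv = 40)
  rata_dataset(rec, meta)
}

# small compound table built through the public constructor path
new_ct_fixture <- function() {
  sl1 <- data.frame(sample = "S1",
                    compound = c("4-Chloro-2-methoxyphenol",
                                 "Ethyl hexanoate", "Vanillin"),
                    area = c(100, 52.34567, 20))
  sl2 <- data.frame(sample = "S2",
                    compound = c("4-Chloro-2-methoxyphenol",
                                 "Ethyl hexanoate"),
                    area = c(200, 33))
  build_compound_table(list(sl1, sl2),
                       meta = data.frame(sample = c("S1", "S2"),
                                         class = c("Scotch", "American")))
}
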