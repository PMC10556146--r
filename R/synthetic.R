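# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

TABLE1_MD5 <- "926cc78f8d0c4416b9d7ae090277d1d7"

#' Model-whisky compositions
#'
#' Loads the packaged model-whisky composition table (two whisky-mimicking
#' solutions of typical aroma compounds in 40% ABV ethanol/water) and
#' expands the cis/trans whisky-lactone row into its two stereoisomer
#' entries, giving 27 compounds for model whisky 1 and 26 for model
#' whisky 2.
#'
#' @return list with data.frames `model1` and `model2` (columns
#'   `compound`, `cas`, `concentration`, ug/mL) and the raw transcription
#'   `table`.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "aromatch",
                      mustWork = TRUE)
  if (unname(tools::md5sum(path)) != TABLE1_MD5)
    stop("model-whisky composition fixture checksum mismatch: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  expand <- function(col) {
    keep <- !is.na(tab[[col]])
    out <- data.frame(compound = tab$compound[keep], cas = tab$cas[keep],
                      concentration = tab[[col]][keep],
                      stringsAsFactors = FALSE)
    i <- match("cis/trans Whisky-lactone", out$compound)
    if (!is.na(i)) {
      iso <- out[c(i, i), ]
      iso$compound <- c("cis-Whisky lactone", "trans-Whisky lactone")
      out <- rbind(out[seq_len(i - 1), ], iso,
                   out[seq(i + 1, length.out = nrow(out) - i), ])
    }
    rownames(out) <- NULL
    out
  }
  list(model1 = expand("model1_ug_ml"), model2 = expand("model2_ug_ml"),
       table = tab)
}

#' Internal-standard spiking composition
#'
#' The two internal standards added to every run: n-undecane and
#' 4-chloro-2-methoxyphenol (43.25 and 48.2 ug/mL).
#'
#' @return data.frame with columns `compound`, `cas`, `concentration`.
#' @export
internal_standards_spec <- function() {
  data.frame(compound = c("n-Undecane", "4-Chloro-2-methoxyphenol"),
             cas = c("1120-21-4", "16766-30-6"),
             concentration = c(43.25, 48.2),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles the instrument-model knobs of the chromatogram generator.
#' Defaults describe a temperature-programmed run sampled at 200 scans/min
#' over m/z 35-250 with Gaussian peaks of width sigma 0.02 min, a detector
#' response of 5e5 area units per ug/mL, additive Gaussian noise and a low
#' flat baseline. Blank runs carry the two contaminants repeatedly seen in
#' procedural blanks (furfural, phenol) at fixed low equivalent
#' concentrations.
#'
#' @param response_factor area units per ug/mL (default 5e5).
#' @param peak_sigma chromatographic peak sigma, minutes (default 0.02).
#' @param noise_sd additive noise sigma, counts (default 50).
#' @param baseline flat baseline, counts (default 20).
#' @param rt_jitter_sd retention-time jitter sigma, minutes (default
#'   0.005).
#' @param scan_rate scans per minute (default 200).
#' @param mz_range integer m/z axis (default 35:250).
#' @param decoy_count library decoys (default 100).
#' @param blank_contaminants named concentrations (ug/mL equivalents) of
#'   blank contaminant peaks.
#' @param seed mandatory RNG seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(response_factor = 5e5, peak_sigma = 0.02,
                              noise_sd = 50, baseline = 20,
                              rt_jitter_sd = 0.005, scan_rate = 200,
                              mz_range = 35:250, decoy_count = 100,
                              blank_contaminants = c(Furfural = 0.80,
                                                     Phenol = 0.10),
                              seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(response_factor > 0, peak_sigma > 0, noise_sd >= 0,
            baseline >= 0, rt_jitter_sd >= 0, scan_rate > 0)
  structure(list(response_factor = response_factor, peak_sigma = peak_sigma,
                 noise_sd = noise_sd, baseline = baseline,
                 rt_jitter_sd = rt_jitter_sd, scan_rate = scan_rate,
                 mz_range = as.integer(mz_range),
                 decoy_count = decoy_count,
                 blank_contaminants = blank_contaminants, seed = seed),
            class = "simulation_config")
}

# curated plausible linear retention indices (polar wax-type column) for
# the model-whisky compounds and internal standards
compound_ri_table <- function() {
  c("beta-Damascenone" = 1815, "Furfural" = 1461, "3-Methylbutanal" = 914,
    "2-Methylbutanal" = 909, "2-Phenylethanol" = 1906,
    "2-Methyl-1-butanol" = 1208, "3-Methyl-1-butanol" = 1209,
    "3-Methylbutyl acetate" = 1122, "2-Phenylethyl acetate" = 1813,
    "3-Methylbutyl octanoate" = 1655, "3-Methylbutyl decanoate" = 1857,
    "Ethyl butanoate" = 1035, "Ethyl hexanoate" = 1233,
    "Ethyl heptanoate" = 1331, "Ethyl octanoate" = 1435,
    "Ethyl decanoate" = 1638, "Ethyl nonanoate" = 1531,
    "Ethyl tetradecanoate" = 2045, "Ethyl hexadecanoate" = 2250,
    "Octanoic acid" = 2060, "Decanoic acid" = 2276,
    "Dodecanoic acid" = 2480, "cis-Whisky lactone" = 1962,
    "trans-Whisky lactone" = 1890, "gamma-Nonalactone" = 2027,
    "2-Methoxyphenol" = 1863, "Phenol" = 2000, "4-Methylphenol" = 2080,
    "4-Ethylphenol" = 2170, "4-Allyl-2-methoxyphenol" = 2164,
    "Vanillin" = 2560, "n-Undecane" = 1100,
    "4-Chloro-2-methoxyphenol" = 2190)
}

# seeded sparse fingerprint spectrum: 5..15 peaks over m/z 35..250
random_fingerprint <- function() {
  n <- sample(5:15, 1)
  mz <- sort(sample(35:250, n))
  inten <- 100 * stats::rbeta(n, 1, 3)
  inten[sample.int(n, 1)] <- 100  # base peak
  mass_spectrum(mz, inten)
}

# n-alkane EI fingerprint: m/z 57 base with the 43/71/85 ladder and
# decreasing higher homolog fragments up to the molecular ion
alkane_spectrum <- function(carbon) {
  mz <- c(43, 57, 71, 85, 99, 113)
  inten <- c(75, 100, 55, 30, 12, 6)
  mwt <- 14 * carbon + 2
  mz <- c(mz[mz < mwt], mwt)
  inten <- c(inten[seq_len(length(mz) - 1)], 3)
  mass_spectrum(mz, inten)
}

#' Build a synthetic spectral library
#'
#' Every composition compound receives a reproducible sparse fingerprint
#' spectrum (5-15 peaks, m/z 35-250) and a plausible retention index from
#' a curated wax-column table (seeded uniform in 650-2550 for names not in
#' it). `decoys` additional entries get independent spectra and RIs; when
#' `decoys >= 10` the last two decoys form an isomer stress-pair (RI 3
#' units apart, spectral cosine >= 0.95) emulating the
#' 3-/4-methylphenol-type confusion. Internal standards are always
#' included.
#'
#' @param spec composition data.frame (columns `compound`, optional `cas`)
#'   or character vector of compound names.
#' @param decoys number of decoy entries (default 0).
#' @param seed mandatory RNG seed.
#' @param contaminants compound names always present in the library even
#'   when absent from the composition (default the procedural-blank
#'   contaminants furfural and phenol; reference libraries deliberately
#'   cover non-sample compounds so blank peaks can be identified).
#' @return list of [library_entry()] objects.
#' @export
make_library <- function(spec, decoys = 0, seed,
                         contaminants = c("Furfural", "Phenol")) {
  if (missing(seed)) stop("a seed is required")
  if (is.data.frame(spec)) {
    names_ <- spec$compound
    cas <- if ("cas" %in% names(spec)) spec$cas else
      rep(NA_character_, length(names_))
  } else {
    names_ <- as.character(spec)
    cas <- rep(NA_character_, length(names_))
  }
  istd <- internal_standards_spec()
  add <- !(istd$compound %in% names_)
  names_ <- c(names_, istd$compound[add])
  cas <- c(cas, istd$cas[add])
  extra <- setdiff(contaminants, names_)
  names_ <- c(names_, extra)
  cas <- c(cas, rep(NA_character_, length(extra)))
  ri_tab <- compound_ri_table()
  with_seed(seed, {
    lib <- lapply(seq_along(names_), function(i) {
      ri <- ri_tab[names_[i]]
      if (is.na(ri)) ri <- stats::runif(1, 650, 2550)
      library_entry(names_[i], unname(ri), random_fingerprint(),
                    cas = cas[i])
    })
    if (decoys > 0) {
      dec <- lapply(seq_len(decoys), function(i)
        library_entry(sprintf("Decoy-%03d", i), stats::runif(1, 650, 2550),
                      random_fingerprint()))
      if (decoys >= 10) {
        # isomer stress-pair: near-identical spectra, RI 3 units apart
        a <- dec[[decoys - 1]]
        pert <- a$spectrum$intensity *
          stats::runif(length(a$spectrum$mz), 0.9, 1.1)
        dec[[decoys]] <- library_entry(sprintf("Decoy-%03d-iso", decoys),
                                       a$ri + 3,
                                       mass_spectrum(a$spectrum$mz, pert))
      }
      lib <- c(lib, dec)
    }
    lib
  })
}

#' Reference alkane retention-time model
#'
#' The ground-truth elution times (minutes) used by the simulator for the
#' C6-C26 n-alkane series: mildly convex in carbon number, emulating a
#' single-ramp temperature program.
#'
#' @param carbon integer carbon numbers.
#' @return retention times in minutes.
#' @export
reference_alkane_times <- function(carbon) {
  1.5 + 0.8 * (carbon - 6) + 0.005 * (carbon - 6)^2
}

#' Ground-truth alkane calibration of the simulator
#' @return an [alkane_calibration()] over C6-C26.
#' @export
reference_calibration <- function() {
  alkane_calibration(6:26, reference_alkane_times(6:26))
}

#' Simulate a chromatogram run
#'
#' Places each composition compound as a Gaussian peak at the retention
#' time of its library RI under the ground-truth calibration (plus seeded
#' RT jitter), with TIC area = concentration x response_factor distributed
#' over the m/z channels proportionally to the compound's library
#' spectrum; adds a flat baseline and Gaussian noise (clamped at 0).
#'
#' @param spec composition data.frame with columns `compound`,
#'   `concentration` (ug/mL).
#' @param lib library (list of [library_entry()]) holding a spectrum and
#'   RI for every composition compound.
#' @param cal ground-truth [alkane_calibration()] (default
#'   [reference_calibration()]).
#' @param cfg a [simulation_config()].
#' @param sample_id sample identifier.
#' @param is_blank flag carried on the matrix.
#' @return list of class `simulated_run`: `matrix` (an
#'   [intensity_matrix()]) and `truth` (data.frame compound, ri, rt, area,
#'   apex per-channel intensities as a list column `apex_spectrum`).
#' @export
simulate_run <- function(spec, lib, cal = reference_calibration(), cfg,
                         sample_id = "run", is_blank = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"))
  lib_names <- vapply(lib, function(e) e$name, character(1))
  miss <- setdiff(spec$compound, lib_names)
  if (length(miss))
    stop("compound(s) missing from library: ", paste(miss, collapse = ", "))
  with_seed(cfg$seed + 1000L * is_blank, {
    dt <- 1 / cfg$scan_rate
    t0 <- cal$rt[1] - 0.5
    t1 <- cal$rt[length(cal$rt)] + 0.5
    times <- seq(t0, t1, by = dt)
    mz_axis <- cfg$mz_range
    X <- matrix(cfg$baseline, length(times), length(mz_axis))
    truth <- data.frame(compound = spec$compound,
                        ri = NA_real_, rt = NA_real_, area = NA_real_)
    apex_list <- vector("list", nrow(spec))
    for (i in seq_len(nrow(spec))) {
      e <- lib[[match(spec$compound[i], lib_names)]]
      rt <- invert_ri(e$ri, cal) + stats::rnorm(1, 0, cfg$rt_jitter_sd)
      area <- spec$concentration[i] * cfg$response_factor
      w <- e$spectrum$intensity / sum(e$spectrum$intensity)
      amp_tot <- area / (cfg$peak_sigma * sqrt(2 * pi))
      g <- exp(-(times - rt)^2 / (2 * cfg$peak_sigma^2))
      ch <- match(e$spectrum$mz, mz_axis)
      ok <- !is.na(ch)
      X[, ch[ok]] <- X[, ch[ok]] + outer(g, amp_tot * w[ok])
      truth$ri[i] <- e$ri
      truth$rt[i] <- rt
      truth$area[i] <- area * sum(w[ok])
      apex_list[[i]] <- stats::setNames(amp_tot * w[ok],
                                        e$spectrum$mz[ok])
    }
    if (cfg$noise_sd > 0)
      X <- X + matrix(stats::rnorm(length(X), 0, cfg$noise_sd),
                      nrow(X), ncol(X))
    X[X < 0] <- 0
    truth$apex_spectrum <- apex_list
    structure(list(matrix = intensity_matrix(times, mz_axis, X, sample_id,
                                             is_blank),
                   truth = truth),
              class = "simulated_run")
  })
}

#' @export
print.simulated_run <- function(x, ...) {
  cat("<simulated_run> ", nrow(x$truth), " planted compounds\n", sep = "")
  print(x$matrix)
  invisible(x)
}

#' Simulate an n-alkane reference run
#'
#' Gaussian alkane peaks (m/z 57 base-peak fingerprints) at the
#' ground-truth calibration times plus seeded jitter, equal areas.
#'
#' @param cfg a [simulation_config()].
#' @param carbons carbon numbers (default 6:26).
#' @param cal ground-truth calibration (default [reference_calibration()]).
#' @param area TIC area per alkane peak (default 2e7).
#' @return list of class `simulated_run` (see [simulate_run()]).
#' @export
simulate_alkane_run <- function(cfg, carbons = 6:26,
                                cal = reference_calibration(),
                                area = 2e7) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed + 77L, {
    dt <- 1 / cfg$scan_rate
    times <- seq(cal$rt[1] - 0.5, cal$rt[length(cal$rt)] + 0.5, by = dt)
    mz_axis <- cfg$mz_range
    X <- matrix(cfg$baseline, length(times), length(mz_axis))
    truth <- data.frame(compound = paste0("C", carbons), carbon = carbons,
                        rt = NA_real_, area = area)
    for (i in seq_along(carbons)) {
      s <- alkane_spectrum(carbons[i])
      rt <- ri_interp(carbons[i] * 100, 100 * cal$carbon, cal$rt) +
        stats::rnorm(1, 0, cfg$rt_jitter_sd)
      w <- s$intensity / sum(s$intensity)
      amp_tot <- area / (cfg$peak_sigma * sqrt(2 * pi))
      g <- exp(-(times - rt)^2 / (2 * cfg$peak_sigma^2))
      ch <- match(s$mz, mz_axis)
      ok <- !is.na(ch)
      X[, ch[ok]] <- X[, ch[ok]] + outer(g, amp_tot * w[ok])
      truth$rt[i] <- rt
    }
    if (cfg$noise_sd > 0)
      X <- X + matrix(stats::rnorm(length(X), 0, cfg$noise_sd),
                      nrow(X), ncol(X))
    X[X < 0] <- 0
    structure(list(matrix = intensity_matrix(times, mz_axis, X, "alkanes"),
                   truth = truth),
              class = "simulated_run")
  })
}

#' Simulate a procedural blank run
#'
#' Contains only the configured blank contaminants (default furfural and
#' phenol) at their low equivalent concentrations.
#'
#' @param lib library providing contaminant spectra and RIs.
#' @param cfg a [simulation_config()].
#' @param cal ground-truth calibration.
#' @return list of class `simulated_run`.
#' @export
simulate_blank <- function(lib, cfg, cal = reference_calibration()) {
  spec <- data.frame(compound = names(cfg$blank_contaminants),
                     concentration = as.numeric(cfg$blank_contaminants),
                     stringsAsFactors = FALSE)
  istd <- internal_standards_spec()
  spec <- rbind(spec, istd[, c("compound", "concentration")])
  simulate_run(spec, lib, cal, cfg, sample_id = "blank", is_blank = TRUE)
}

#' Simulate a two-class RATA sensory panel
#'
#' Latent-intensity model: for panellist p, sample s, attribute a the
#' latent value is `mu_a + effect_a * I(class_s == target) + b_p + eps`
#' with seeded attribute baselines `mu_a ~ N(0, 0.5)`, panellist biases
#' `b_p ~ N(0, 0.3)` and unit noise. Per panellist-sample the at most 5
#' attributes with the largest latent values above a check threshold are
#' checked and rated 1-3 by fixed latent cutpoints. Fully deterministic
#' under the seed.
#'
#' @param samples data.frame with columns `sample`, `class`, `abv`
#'   (default: the 16-whisky set at 20% and 40% ABV from
#'   [whisky_sample_set()]).
#' @param effects named numeric vector over [rata_attributes()]: latent
#'   mean shift (in noise SD units) applied to `target_class` samples.
#'   Missing names default to 0.
#' @param n_panellists panel size (default 11).
#' @param target_class class receiving the shifts (default `"American"`).
#' @param seed mandatory RNG seed.
#' @param check_threshold latent value above which an attribute can be
#'   checked (default 0.8).
#' @return a [rata_dataset()]; `sample_meta` carries `sample`, `whisky`,
#'   `class`, `abv`.
#' @export
simulate_panel <- function(samples = whisky_sample_set(),
                           effects = numeric(0), n_panellists = 11,
                           target_class = "American", seed,
                           check_threshold = 0.8) {
  if (missing(seed)) stop("a seed is required")
  attrs <- rata_attributes()
  eff <- stats::setNames(numeric(length(attrs)), attrs)
  if (length(effects)) {
    bad <- setdiff(names(effects), attrs)
    if (length(bad)) stop("unknown attributes in effects: ",
                          paste(bad, collapse = ", "))
    eff[names(effects)] <- effects
  }
  with_seed(seed, {
    mu <- stats::rnorm(length(attrs), 0, 0.5)
    bias <- stats::rnorm(n_panellists, 0, 0.3)
    rows <- vector("list", n_panellists * nrow(samples))
    k <- 0L
    for (p in seq_len(n_panellists)) {
      for (s in seq_len(nrow(samples))) {
        latent <- mu + eff * (samples$class[s] == target_class) +
          bias[p] + stats::rnorm(length(attrs))
        ord <- order(latent, decreasing = TRUE)
        checked <- ord[seq_len(5)]
        checked <- checked[latent[checked] > check_threshold]
        if (length(checked)) {
          inten <- 1L + (latent[checked] > check_threshold + 0.8) +
            (latent[checked] > check_threshold + 1.6)
          k <- k + 1L
          rows[[k]] <- data.frame(panellist = sprintf("P%02d", p),
                                  sample = samples$sample[s],
                                  attribute = attrs[checked],
                                  intensity = as.integer(inten),
                                  stringsAsFactors = FALSE)
        }
      }
    }
    rec <- do.call(rbind, rows[seq_len(k)])
    rata_dataset(rec, samples)
  })
}

#' The default 16-whisky sample set
#'
#' Nine Scotch and seven American whiskies, each at 20% and 40% ABV
#' (the two dilutions evaluated by the panel).
#'
#' @param abv_levels ABV levels per whisky (default `c(20, 40)`).
#' @return data.frame with columns `sample`, `whisky`, `class`, `abv`.
#' @export
whisky_sample_set <- function(abv_levels = c(20, 40)) {
  whisky <- c(sprintf("S%02d", 1:9), sprintf("A%02d", 1:7))
  class <- rep(c("Scotch", "American"), c(9, 7))
  out <- do.call(rbind, lapply(abv_levels, function(abv)
    data.frame(sample = sprintf("%s_%d", whisky, abv), whisky = whisky,
               class = class, abv = abv, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Simulate a two-class compound table with planted class signal
#'
#' Emulates the semi-quantitative sample x compound relative-area matrix
#' of a two-class sample set. Compound abundance scales are log-normal
#' (relative areas in aroma extracts span orders of magnitude, so total
#' variance concentrates in a handful of major compounds, which is what
#' makes an unsupervised PCA reduction viable before LDA); the
#' `n_informative` compounds with the largest scales carry the class
#' signal: their class-mean difference is `effect` pooled within-class
#' standard deviations. All other compounds are uninformative noise.
#'
#' @param n_class1,n_class2 samples per class (defaults 9 Scotch,
#'   7 American).
#' @param n_compounds total number of compounds (default 200).
#' @param n_informative compounds carrying class signal (default 4).
#' @param effect class-mean shift in pooled within-class SDs (default 2).
#' @param sdlog log-scale spread of compound abundance scales
#'   (default 1.5).
#' @param seed mandatory RNG seed.
#' @return list with `table` (a `compound_table`), `feature_matrix` (a
#'   [feature_matrix()]), and `informative` (planted compound names).
#' @export
simulate_compound_table <- function(n_class1 = 9, n_class2 = 7,
                                    n_compounds = 200, n_informative = 4,
                                    effect = 2, sdlog = 1.5, seed) {
  if (missing(seed)) stop("a seed is required")
  with_seed(seed, {
    n <- n_class1 + n_class2
    y <- rep(c("Scotch", "American"), c(n_class1, n_class2))
    sd_j <- exp(stats::rnorm(n_compounds, 0, sdlog))
    inf <- order(sd_j, decreasing = TRUE)[seq_len(n_informative)]
    mu_j <- 5 * sd_j
    X <- vapply(seq_len(n_compounds), function(j)
      mu_j[j] + stats::rnorm(n, 0, sd_j[j]), numeric(n))
    for (j in inf)
      X[y == "American", j] <- X[y == "American", j] + effect * sd_j[j]
    X[X < 0] <- 0
    nm <- sprintf("compound_%03d", seq_len(n_compounds))
    samples <- c(sprintf("S%02d", seq_len(n_class1)),
                 sprintf("A%02d", seq_len(n_class2)))
    meta <- data.frame(sample = samples, class = y,
                       stringsAsFactors = FALSE)
    tab <- new_compound_table(samples, nm, X, meta)
    list(table = tab, feature_matrix = feature_matrix(X, y, nm),
         informative = nm[inf])
  })
}

#' Sensory feature matrix from an aggregated two-dilution panel
#'
#' One row per whisky: the RATA attribute means at each ABV level
#' concatenated (e.g. 17 attributes x 2 levels = 34 features for the
#' default panel), with the whisky's class label.
#'
#' @param sm a `sensory_matrix` from [aggregate_rata()] whose
#'   `sample_meta` has columns `whisky`, `class`, `abv`.
#' @return a [feature_matrix()].
#' @export
sensory_feature_matrix <- function(sm) {
  stopifnot(inherits(sm, "sensory_matrix"))
  meta <- sm$sample_meta
  if (!all(c("whisky", "abv") %in% names(meta)))
    stop("sample_meta needs whisky and abv columns")
  whiskies <- unique(meta$whisky)
  abvs <- sort(unique(meta$abv))
  blocks <- lapply(abvs, function(a) {
    ids <- meta$sample[match(paste(whiskies, a),
                             paste(meta$whisky, meta$abv))]
    b <- sm$rata_mean[match(ids, rownames(sm$rata_mean)), , drop = FALSE]
    colnames(b) <- paste0(colnames(b), "_", a)
    b
  })
  X <- do.call(cbind, blocks)
  rownames(X) <- whiskies
  y <- meta$class[match(whiskies, meta$whisky)]
  feature_matrix(X, y)
}
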