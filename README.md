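# aromatch

Semi-automated GC–MS aroma profiling and two-class sample classification,
built for rapid characterization of complex aroma extracts such as whisky.
The package covers the full chain from raw chromatogram to classified
sample set:

1. **Raw data processing** — chromatograms as scan × m/z unit-mass
   intensity matrices (ANDI-MS netCDF via `mzR`, or a long CSV dialect),
   moving-average noise reduction, and Biller–Biemann style peak
   deconvolution: scans where enough m/z channels place coincident local
   maxima become component apexes, each with a baseline-corrected spectrum
   and TIC area.
2. **Retention-index calibration** — detection of a C6–C26 n-alkane
   series (m/z 57 base-peak fragment ladder) and conversion of retention
   times to linear retention indices after van den Dool & Kratz:
   `RI = 100 n + 100 (t − t_n) / (t_{n+1} − t_n)`.
3. **Compound identification** — every component is scored against an
   MSP-style reference library by the spectral cosine

   `score_MS = Σᵢ aᵢ bᵢ / (√Σ aᵢ² · √Σ bᵢ²)`

   combined with the retention-index mismatch,

   `score_MS+RI = 1 − [(1 − score_MS) + |RI − RI_lib| / RI_lib] / 2`,

   zeroed outside a ±30 index-unit window. Identities are proposed above a
   free threshold (default 0.8); blank contaminants are removed when the
   sample/blank area ratio falls below 3; areas are reported relative to
   the internal standard 4-chloro-2-methoxyphenol.
4. **Sensory statistics** — rate-all-that-apply (RATA) panel records are
   split into intensity means and check-all-that-apply (CATA) citation
   proportions; per-attribute significance by Cochran's Q; sample mapping
   by principal coordinate analysis.
5. **Classification** — two-class Fisher LDA (ridge-regularized when
   features outnumber samples) inside a repeated-subsampling protocol:
   5000 repetitions of random 13/3 train/test splits of 16 samples (560
   possible splits), stratified 5-fold cross-validation per repetition,
   optional preceding PCA, and a per-feature *delta predictor* influence
   measure (sd-standardized mean absolute discriminant weight, scaled to
   mean 1). The headline metric is the percentage of repetitions with a
   perfect test triple.
6. **Synthetic data** — a fully seeded generator for model-whisky
   chromatograms (the packaged 27/26-compound composition table), alkane
   reference runs, procedural blanks, spectral libraries with decoys and
   isomer stress-pairs, two-class RATA panels, and planted-signal compound
   tables — every pipeline stage is testable against known ground truth.

## Worked example

Simulate model whisky 1 (27 aroma compounds plus two internal standards)
with a 100-decoy library, calibrate on a synthetic alkane run, identify at
threshold 0.8 with blank subtraction, then classify a sensory panel with a
planted caramel difference between Scotch and American samples:

```r
library(aromatch)

t1 <- load_table1()
composition <- rbind(t1$model1[, c("compound", "concentration")],
                     internal_standards_spec()[, c("compound", "concentration")])

lib <- make_library(t1$model1, decoys = 100, seed = 1)
cfg <- simulation_config(seed = 1)
cal <- detect_alkanes(denoise(simulate_alkane_run(cfg)$matrix, 5, 150),
                      6:26, min_area = 1e4)

run   <- simulate_run(composition, lib, cfg = cfg, sample_id = "model1")
blank <- simulate_blank(lib, cfg)
blank_list <- detect_compounds(blank$matrix, cal, lib)
hits <- detect_compounds(run$matrix, cal, lib, threshold = 0.8,
                         blank = blank_list)
head(hits[, c("compound", "ri_observed", "ri_lib", "score_ms_ri", "area")])
#>                compound ri_observed ri_lib score_ms_ri      area
#> 1       Ethyl butanoate    1036.257   1035   0.9993926  150010.3
#> 2 3-Methylbutyl acetate    1121.765   1122   0.9998951 1209868.1
#> 3    3-Methyl-1-butanol    1209.302   1209   0.9995884 5105035.4
#> 4       Ethyl hexanoate    1233.140   1233   0.9999434 1825027.6
#> 5      Ethyl heptanoate    1331.429   1331   0.9998390  195036.1
#> 6       Ethyl octanoate    1434.659   1435   0.9998812 1615030.5

sum(t1$model1$compound %in% hits$compound)   # 23 of 27 recovered
mean(hits$compound %in% composition$compound) # precision 1.00
```

23 of the 27 planted compounds survive the full pipeline with no false
identities; the misses are the trace-level β-damascenone and the
co-eluting isomer pairs (2-/3-methylbutanal, 2-/3-methyl-1-butanol), which
merge into single components — the characteristic failure modes of
coincident-maxima deconvolution.

```r
panel <- simulate_panel(effects = c(caramel = 2), seed = 1)
fm <- sensory_feature_matrix(aggregate_rata(panel))
res <- run_protocol(fm, reps = 5000, seed = 1)
res
#> <lda_protocol> 5000 repetitions, 13/3 split, 5-fold CV
#>   perfect test repetitions: 100.00%
#>   mean test accuracy:       100.00%
#>   mean CV accuracy:         100.00%
#>   distinct training subsets realized: 560
head(res$delta, 3)
#>      feature influence flagged
#> 1 caramel_40  4.516458    TRUE
#> 2 caramel_20  3.964189    TRUE
#> 3   melon_20  2.305454    TRUE
```

The planted caramel shift dominates the delta-predictor ranking at both
dilution levels, and every one of the 560 possible training subsets is
realized within the 5000 repetitions.

A thin command-line wrapper over the same functions is included at
`inst/cli/aromatch.R` (subcommands `calibrate`, `deconvolve`, `detect`,
`table`, `sensory`, `classify`).

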