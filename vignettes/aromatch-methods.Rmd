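---
title: "Methods: semi-automated GC-MS aroma profiling and two-class classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automated GC-MS aroma profiling and two-class classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, algorithms and design choices behind
`aromatch`: what each stage computes, which parameters matter, what the
synthetic-data generator does and does not emulate, and where the design
was genuinely open.

## The problem

Characterizing the volatile (aroma) composition of a complex extract —
whisky is the motivating case — by GC–MS normally requires slow,
expert-driven work: peak picking, spectral interpretation, retention-index
comparison, and confirmation against reference standards. `aromatch`
implements the *semi-automated* alternative: deterministic deconvolution
of the chromatogram, automated identity *proposition* against a spectral
library using both mass-spectral and retention-index evidence, and
downstream statistics that classify sample sets from the resulting
compound tables and from rapid sensory (RATA) panels. Identity
propositions are exactly that — the pipeline never claims unequivocal
identification, which would require reference standards and olfactometry.

## Chromatogram model and deconvolution

A chromatogram is a scan × m/z matrix of non-negative intensities with
strictly increasing scan times (minutes). Unit-mass binning (round half
away from zero, intensities within a bin summed) is applied on input; it
preserves each scan's total ion current exactly.

**Noise reduction** is a centered moving average per m/z channel
(`window` scans, odd, default 5; edges average over the scans available)
followed by flooring: intensities below `min_intensity` become 0. With
the default synthetic noise (σ = 50 counts on a baseline of 20) the
default floor of 150 counts ≈ baseline + 6 standard errors of the
smoothed noise, which empties signal-free regions while leaving analyte
peaks (≥ 10× noise at apex) untouched. The floor matters: coincident-
maxima deconvolution counts local maxima per channel, and unfloored noise
produces maxima everywhere.

**Component detection** is the classic coincident-ion-maxima scheme: a
scan where at least `min_channels` (default 3) channels place a local
maximum within ± `apex_window` (default 2) scans is a candidate apex;
runs of candidates collapse to the largest-TIC scan; apexes closer than
`apex_window` merge, keeping the larger TIC. Ties between equal-intensity
neighbouring scans resolve to the earlier scan, making output
deterministic. Each component's spectrum holds the agreeing channels'
apex intensities above a per-channel linear baseline chord between the
channel's flanking minima; the component area is the trapezoidal TIC
integral between the flanking TIC minima, corrected by the chord between
them, clamped at zero. The linear chord is the simplest baseline model
that keeps areas comparable across runs with different background levels;
no curve resolution is attempted, so co-eluting compounds closer than
roughly the apex window merge into one component with a mixed spectrum —
visible in practice as the loss of 2-methyl-1-butanol next to abundant
3-methyl-1-butanol.

## Retention-index calibration

The alkane detector runs the deconvolution on a reference chromatogram,
keeps components whose spectra show the n-alkane fragment ladder (base
peak m/z 57 with 43/71/85 present) — which makes carbon-number assignment
robust to contaminant peaks — and takes the expected number of
largest-area survivors in elution order. Retention indices follow the
temperature-programmed (van den Dool–Kratz) form, piecewise linear with
value 100·n at the C_n apex. Linear extrapolation beyond the terminal
alkanes is allowed up to 50 index units and is an error beyond that: the
±30-unit identification window makes longer extrapolations meaningless.
The inverse mapping (`invert_ri`) is exact to 1e-9 and is what the
simulator uses to place peaks at target indices.

## Identification score

Spectra are compared by cosine similarity on the shared integer m/z axis
(bins 1..5000, absent bins zero). The axis is read as *all integer*
unit-mass positions; restricting to even-numbered bins would discard half
the signal and contradict the 35–399 acquisition range. Cosine is
scale-invariant, so library normalization conventions are immaterial.
The combined score averages the spectral shortfall with the relative RI
mismatch,

$$\mathrm{score}_{MS+RI} = 1 - \frac{(1 - \mathrm{score}_{MS}) +
  |RI - RI_{lib}|/RI_{lib}}{2},$$

multiplied by a hard window that zeroes candidates more than 30 index
units away. At an exact RI match the combined score is
\((1 + \mathrm{score}_{MS})/2\): RI agreement alone can never carry an
identification past a 0.8 threshold without spectral support
(score_MS ≥ 0.6 is needed). Matches at or above the threshold are ranked
by combined score; ties break by smaller |ΔRI|, then library order (the
tie rule is this package's choice; any deterministic rule would do).
Per sample, each compound name is kept once — the occurrence with the
largest area — and areas are reported relative to the
4-chloro-2-methoxyphenol internal standard.

**Blank subtraction** removes compounds present in both sample and blank
with a sample/blank area ratio *strictly* below 3 (a ratio of exactly 3
is kept); compounds absent from the blank are kept, blank-only compounds
ignored, and a zero blank area counts as an infinite ratio. The stage is
off by default and enabled for validation against procedural blanks,
matching how such blanks are used in practice for model solutions but not
for routine sample batches.

## Sensory statistics

RATA records (panellist × sample × attribute, intensity 0–3 where 0 means
"not checked", at most 5 checked attributes per panellist–sample) split
into intensity means (sum of ratings / panel size) and CATA citation
proportions. The free-text "other" attribute is stored but excluded from
all statistics. Attribute significance uses Cochran's Q over samples with
panellists as blocks — the standard test inside CATA analysis tools —
with a χ² reference distribution on (samples − 1) degrees of freedom;
attributes with no variation are degenerate (p = 1). Sample maps come
from classical scaling (PCoA) of Euclidean distances on the citation
proportions; with a Euclidean distance the coordinates reproduce the
pairwise distances exactly, and negative eigenvalues (impossible here)
would be dropped and logged. The distance choice was open; Euclidean on
proportions keeps the map metric and the reconstruction exact.

## Classification protocol

The discriminant is the two-class Fisher LDA,
\(w \propto \Sigma_{pooled}^{-1}(\mu_A - \mu_B)\), with the decision
threshold at the midpoint of the projected class means. When the pooled
covariance is singular — the normal situation with hundreds of compounds
and 13 training samples — a ridge term λI with
λ = 1e-6 · trace(Σ)/p is added; the scale-relative form keeps the
regularization unit-free.

The protocol draws, per repetition, a uniform random test set of 3 of the
16 samples (redrawing, with a logged count, if a class would vanish from
training), optionally projects onto the leading principal components
fitted on the training samples only (centering, no scaling — the variance
structure is the point of the reduction), records a stratified 5-fold
cross-validated training accuracy, fits on all 13 and scores the 3 test
samples. With 16 samples there are exactly 560 distinct training sets;
at 5000 repetitions every one is realized in practice and the subset log
lets the user verify it. Three summaries are reported: the *perfect
rate* (share of repetitions with all 3 test samples correct — the
headline), mean test accuracy, and mean CV accuracy. Per-repetition test
accuracy is necessarily one of {0, 1/3, 2/3, 1}.

The *delta predictor* for feature j is the mean over repetitions of
|w_j| · sd_j, with sd_j the pooled within-class standard deviation over
the full data, rescaled so the mean influence is 1; features above 2.0
are flagged as top predictors. The sd-standardization makes the measure
invariant to feature rescaling — exactly so in the full-rank (ridge-free)
case, and to within the ridge's small scale coupling otherwise. The
formula is this package's definition of an influence measure that is
shown only graphically in classification practice; any monotone variant
(e.g. |w_j| · overall sd) ranks features almost identically.

## The synthetic-data generator

The generator exists so that every stage can be tested against known
ground truth; it emulates the *structure* of SBSE-GC–MS aroma data, not
its physics.

* **Compositions**: the packaged model-whisky table (27 and 26 compounds,
  with the cis/trans whisky-lactone row expanded to two stereoisomer
  entries, each carrying the printed concentration) plus internal
  standards at 48.2 and 43.25 µg/mL.
* **Chromatograms**: each compound is a Gaussian peak (σ = 0.02 min) at
  the retention time of its library RI under a fixed convex alkane-time
  model, sampled at 200 scans/min over m/z 35–250, with TIC area =
  concentration × 5e5 counts·min per µg/mL split across channels in
  proportion to the compound's library spectrum, plus a flat baseline
  (20 counts), Gaussian noise (σ = 50) and RT jitter (σ = 0.005 min,
  ≈ 0.6 index units). A uniform response factor is a deliberate
  simplification: real SBSE extraction discriminates strongly by
  polarity, which is why trace polar analytes are the first casualties in
  real data. Retention indices for the composition compounds come from a
  curated table of plausible wax-column values; close isomer pairs
  (2-/3-methylbutanal at RI 909/914, the butanols at 1208/1209) are
  deliberately retained so the simulator reproduces the co-elution
  failure modes of real processing.
* **Libraries**: reproducible sparse fingerprint spectra (5–15 peaks,
  m/z 35–250), seeded decoys with independent spectra and RIs, an isomer
  stress-pair (RI 3 apart, cosine ≥ 0.95) once at least 10 decoys are
  requested, and the procedural-blank contaminants always present (real
  reference libraries deliberately include non-sample compounds).
  Spectra are synthetic fingerprints, not EI fragmentation predictions.
* **Blanks**: furfural and phenol at 0.80 and 0.10 µg/mL equivalents —
  chosen once so the ratio-3 rule behaves as observed with real blanks:
  furfural survives subtraction where its sample concentration is high
  (model 1, ratio 3.8) and is removed where it is low (model 2,
  ratio 1.9), phenol is always removed.
* **Panels**: 11 panellists, 17 attributes, max 5 checks, intensities
  1–3 by latent-value cutpoints; class effects enter as latent mean
  shifts in noise-SD units. With zero effects the design is exchangeable
  across samples, so Cochran's Q holds its nominal size.
* **Compound tables**: log-normal abundance scales (spread 1.5 log units)
  concentrate total variance in a handful of major compounds — mirroring
  real semi-quantitative tables, where a preceding 4-component PCA can
  capture >95% of variance — and the informative compounds sit among
  those majors with a class-mean shift of 2 pooled within-class SDs.

What passing tests on these data do **not** show: robustness to drifting
baselines, tailing peaks, matrix effects, response nonlinearity, real EI
spectral similarity between congeners, or panellist idiosyncrasies. The
generator's co-elution behaviour is geometric (peak spacing vs. apex
window), not thermodynamic.

## Numerical choices and degenerate inputs

* Unit-mass binning rounds half away from zero; base R's `round` (half to
  even) would split x.5 masses inconsistently across scans.
* Local-maximum ties and plateaus resolve to the earlier scan.
* A component apex at the matrix edge integrates one-sided, with a
  message.
* `score_ms` is clamped to ≤ 1 against floating-point overshoot; the
  all-zero spectrum is unconstructable by the `mass_spectrum` validator,
  so the cosine's undefined case cannot arise from package objects.
* Cochran's Q returns p = 1 for attributes with no variation rather than
  NaN.
* PCoA drops eigenvalues below 1e-8 of the largest magnitude; explained
  proportions are taken over the positive spectrum.
* LDA training draws that lose a class are redrawn rather than skipped,
  keeping the repetition count fixed; the redraw count is reported.
* All generators take a mandatory seed and restore the caller's RNG
  state, so a fixed seed fixes every downstream result exactly.

## Problem sizes used in the test suite

The suite exercises the pipeline at sizes chosen to keep full runs fast
while preserving the failure modes of interest: chromatograms of ~400–
4000 scans × 46–216 channels; 50 seeded deconvolution simulations with 6
planted peaks each at SNR 10–50; one full model-whisky run against a
133-entry library (27 compounds + standards + contaminant + 100 decoys
plus a stress pair); classification at the full 5000 repetitions for the
planted-signal and sensory checks and 2000 repetitions against the
exhaustive 560-split enumeration for the label-shuffled null; 2000 null
attributes for the Cochran's Q size check.

## Known limitations

* Coincident-maxima deconvolution cannot separate compounds co-eluting
  within the apex window; the one-occurrence-per-compound rule then
  silently prefers the larger peak.
* The perfect-rate criterion for planted-signal recovery depends on the
  realized sample draw: with 4 informative features at effect size 2 the
  per-sample Bayes error is ≈ 2%, so a minority of generated 16-sample
  sets contain one inherently ambiguous sample, capping the perfect rate
  well below 100% for those draws. The packaged check reports the
  default-seed dataset as-is.
* The ±30 RI window is hard; a compound whose observed index drifts past
  it is lost regardless of spectral quality.
* Relative areas are semi-quantitative: no response calibration, no
  odor-activity weighting.
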