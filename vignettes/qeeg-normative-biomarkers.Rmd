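---
title: "Normative z-score QEEG biomarkers: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative z-score QEEG biomarkers: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegnorm)
```

## The analysis in one paragraph

`qeegnorm` turns a 5-minute eyes-closed resting EEG (19 channels of the
10/20 system, linked-ear reference, 256 Hz) into two per-subject, per-band
biomarkers: the mean z-score of absolute band power over the 19
electrodes, and the number of electrodes whose z exceeds 1.96 — the upper
2.5% of an age-matched normative distribution. The chain is: acquisition
filtering (0.5–70 Hz bandpass, 60 Hz notch) → down-sampling to 128 Hz →
automated artifact rejection on the continuous record → non-overlapping
2-s epochs, requiring ≥ 60 s of clean data → epoch-averaged FFT absolute
power on a 0.5 Hz grid (0.5–30 Hz), gated on split-half and test–retest
reliability > 0.90 in every channel → band aggregation (delta 0.5–4,
theta 4–8, alpha 8–12, beta 12–25, high beta 25–30 Hz) → z-scoring
against an age-stratified normative database → biomarker reduction,
pre/post-treatment deltas, and the cohort statistical layer
(Mann–Whitney, Wilcoxon signed-rank, chi-square/Fisher, crude and
multivariable logistic odds ratios with Wald intervals).

Because clinical registries and commercial normative databases are not
redistributable, the package ships a synthetic generator for all of it:
resting EEG with a controlled spectrum, a normative reference cohort with
age trends, and clinical cohorts with group structure (three migraine
subtypes, disease controls, healthy controls), follow-up recordings and
covariates. Every downstream stage is tested against this generator.

## The z-score model

For subject power $X$ in a channel × band cell, the standardized score is

$$z = \frac{T(X) - \mu_{a}}{\sigma_{a}},$$

where $\mu_a$, $\sigma_a$ are the mean and SD (n−1 denominator) of $T(X)$
across reference subjects in the subject's age bin and $T$ is the
normative transform. The default $T = \log_{10}$: raw µV² band power is
strongly right-skewed, and interpreting $z > 1.96$ as "top 2.5%" presumes
approximate Gaussianity, which holds for log power but fails badly for
raw power. The identity transform is retained (`transform = "identity"`)
for strict raw-power fidelity; it is a flagged configuration choice, not
the default. An electrode is counted when $z$ *strictly* exceeds the
threshold; ties at 1.96 are excluded.

Age bins default to 5-year widths. Wider bins admit more reference
subjects per cell (smaller finite-sample error, see Calibration) at the
cost of absorbing the age trend into the within-bin variance; analyses in
this package's own acceptance runs use 20-year adult bins over ages
20–60, stated where used.

## The synthetic generator

Each channel's spectrum is built in the frequency domain and inverted
with random phases (so the target spectrum is exact up to leakage):

* a $1/f^{\beta}$ background, default $\beta = 1.5$ (typical of
  eyes-closed resting EEG), scaled to ~µV²/Hz magnitudes with a
  posterior-dominant Gaussian alpha bump (center 10 Hz, width 0.8 Hz);
* per-cell (channel × band) multiplicative log-power factors:
  a fixed smooth age trend (delta and theta fall steeply through
  childhood maturation and are nearly flat in adulthood; alpha declines
  linearly with adult age), an inter-subject random effect
  $N(0, s^2)$ with $s = 0.25$ decades, and the *injected offset*
  $\delta \cdot s$, where $\delta$ is expressed in normative-SD units —
  because the normative cohort is generated with the same $s$, an offset
  of $\delta$ moves the expected z by ≈ $\delta$;
* optional artifacts: blinks (0.3 s, ≥150 µV, frontally weighted),
  muscle bursts (30–70 Hz), flatline segments — each built to trip one
  of the three rejection rules;
* the log-gain profile is smoothed across band edges with a 0.5 Hz
  half-width so that the (small) spectral leakage across an edge carries
  the same gain as the band it lands in (see Calibration).

Group offset profiles for the clinical cohorts are simulator
configuration tuned so that group-median biomarkers land in the
clinically reported range: high-beta offsets 1.30/1.50/1.75 SD for the
low-frequency episodic, high-frequency episodic and chronic migraine
groups (ordered supra-threshold electrode-count medians near the
reported 5/6/8), 0.75–0.80 for controls (median near 3), and smaller
elevations in the other bands.
The ordering LF-EM ≤ HF-EM ≤ CM in high beta is enforced at spec
validation. Treatment response multiplies a follow-up recording's offsets
by `treatment_effect` (default 0.5); deterioration by 1.25.

What the generator does *not* emulate: volume conduction and channel
covariance (cells are independent given the subject), non-stationarity
within a session, drowsiness, medication effects, or any migraine
pathophysiology beyond band-power elevation. Passing tests therefore
demonstrate that the analysis machinery is correct and calibrated, not
that the clinical effect sizes are reproduced from first principles.

## Signal-path choices

**Zero-phase filtering.** The acquisition chain is a 4th-order
Butterworth bandpass plus an RBJ biquad notch (Q = 30). Both are applied
as their squared-magnitude frequency response — exactly the response of a
forward–backward (filtfilt) pass — by multiplying each channel's
spectrum. This avoids phase distortion of epochs, is ~6× faster in pure R
than sample-domain filtfilt, and differs from it only in edge handling
(circular rather than reflected padding), immaterial for multi-minute
stationary records. Down-sampling uses a Hamming-windowed order-64 FIR
anti-alias filter (cutoff at the target Nyquist) applied the same way,
delay-compensated, followed by integer decimation.

**Artifact rules.** The original clinical workflow combined visual
inspection with proprietary algorithms; the package substitutes three
transparent per-channel rules on the continuous record — amplitude
(±100 µV), gradient (50 µV/sample), and flatline (variance < 0.1 µV²
over 1-s sliding windows) — unioned across channels and padded by 0.5 s.
Thresholds are exposed in `artifact_config()`. Epochs are cut on a grid
anchored at sample 0 and never re-anchored; any window touching a bad
sample is dropped.

**Reliability.** Split-half correlates the mean log10 power spectra (60
bins) of odd- vs even-indexed retained epochs, per channel; test–retest
uses first vs second temporal halves. Correlations on log power, because
raw power correlations are dominated by delta. The recording passes only
if both metrics exceed 0.90 in *every* channel (strict; an undefined
correlation fails). The epoch-selection loop of the commercial software
is simplified to gate-and-exclude.

**Taper.** `epoch_power()` defaults to a plain rectangular FFT, which
keeps the textbook conventions (a bin-aligned sinusoid of amplitude A
lands in one bin with power A²/2; Parseval holds exactly). The pipeline
configuration, however, defaults to a Hann taper
(`pipeline_config(taper = "hann")`): with rectangular epochs the −13 dB
sidelobes mix power across band edges, and because neighboring bands
carry different (lognormal) gains this mixture makes band log power
right-skewed, which visibly inflates the null exceedance rate at z =
1.96. The Hann taper (−31 dB sidelobes) removes the effect. `"none"`
restores the plain-FFT convention.

## Calibration of the 2.5% tail

Two small but systematic effects displace the null flag rate from the
nominal 2.5%:

1. **Finite reference cohort.** With $n$ reference subjects per cell,
   $(X - \hat\mu)/\hat\sigma \sim t_{n-1}\sqrt{1 + 1/n}$, so the true
   exceedance probability at 1.96 is ≈ 2.7% at n = 100 and ≈ 2.6% at
   n = 200–300. This is inherent to any finite normative database and is
   the reason acceptance runs use a few hundred reference subjects in
   wide bins rather than many sparse bins.
2. **Distributional shape.** Any right-skew of the per-cell log-power
   distribution inflates the tail further (an Edgeworth term of roughly
   $\varphi(1.96)\,\gamma_1/6\,(1.96^2-1)$, i.e. +0.4 percentage points
   per 0.15 of skewness). Three generator/analysis interactions were
   found to create such skew and are designed away: untapered cross-band
   leakage (fixed by the Hann default), leakage from beyond the 0.5–30 Hz
   grid carrying no gain (fixed by extending band gains past the grid
   edges), and exponential-in-age trend components inside adult age bins
   (fixed by flattening the maturation trends in adulthood).

After these choices the measured null rate matches the finite-reference
expectation within Monte-Carlo error, band by band.

## Statistical layer conventions

* Mann–Whitney U and Wilcoxon signed-rank are implemented with exact
  enumeration for small samples (combined n ≤ 12, resp. ≤ 15 nonzero
  pairs; ties handled by ½-counts and average ranks, two-sided p by the
  doubling rule) and tie-corrected normal approximation with continuity
  correction otherwise. Both routes are verified against brute-force
  enumeration oracles in the test suite.
* 2×2 tables use Pearson chi-square without continuity correction, or
  Fisher's exact test when any expected cell is ≤ 5 (Cochran's rule).
  Zero margins are errors.
* Crude odds ratios use the cross-product with the Wald interval
  $\exp(\ln \text{OR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$; zero cells are
  an error unless the Haldane–Anscombe 0.5 correction is requested.
* The multivariable model is a maximum-likelihood logistic fit (IRLS,
  tolerance 1e-8, ≤ 100 iterations), complete cases only, Wald CIs. Sex
  is coded female = 1 so the odds ratio reads female vs male. Perfect
  separation and non-convergence are errors, never silent estimates.
* Shapiro–Wilk at p < .05 switches descriptives to median
  (25th–75th percentile). No multiple-testing correction is applied,
  matching common practice in this literature.
* The subtype rules: chronic migraine = ≥ 15 monthly headache days with
  ≥ 8 migraine headache days; else high-frequency episodic at 8–14 MHD;
  else low-frequency episodic. Increased middle-cerebral-artery mean
  flow velocity is a strict > 70 cm/s; missing Doppler values exclude the
  subject from TCD analyses only.

## Degenerate inputs and tie-breaks

* A recording missing any of the 19 channels fails loading, naming the
  absentees; modern T7/T8/P7/P8 labels alias to T3/T4/T5/T6.
* A reference bin with < 5 subjects, or any zero-SD cell, aborts
  database construction; ages outside populated bins are never
  extrapolated.
* All-zero paired differences give a defined Wilcoxon result (p = 1)
  with a warning; empty groups are errors.
* Pre/post deltas are pre − post, so improvement (falling power) is a
  positive difference; they refuse to combine summaries computed with
  different thresholds or databases.

## Problem sizes used in the package's own runs

Monte-Carlo checks in the test-suite and the acceptance script use
120-second recordings (60 epochs, comfortably past the 60-s gate after
clean-artifact rejection), a synthetic normative database of several
hundred subjects in two 20-year adult bins, 100-subject null cohorts for
tail calibration, and cohorts of ~40 subjects per migraine subtype across
10 seeds for the ordering and recovery checks. These sizes were chosen so
that each check's Monte-Carlo error is small against the quantity it
measures; the full 5-minute default (`duration_s = 300`) remains the
generator default for ordinary use.

## Known limitations

* The normative builder uses discrete age bins, not regression-based
  continuous-age norms; z-scores jump at bin boundaries.
* The EDF writer targets plain continuous EDF (16-bit, 1-s records,
  microvolts) — no EDF+ annotations or discontinuous records.
* Reliability gating excludes whole recordings; the optional greedy
  epoch-pruning loop of commercial software is not implemented.
* The statistical layer models the study's design only: no propensity
  adjustment, imputation, or survival analysis.
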