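---
title: "Methods: band-resolved ECoG/EMG analysis and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band-resolved ECoG/EMG analysis and the synthetic cohort}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and numerical choices behind
`ecogemg`, in the spirit of a methods section: what each stage computes,
which parameters matter, what the synthetic-cohort generator does and does
not emulate, and where the design was genuinely open.

## The experimental design the package models

The package targets longitudinal rodent experiments of the
cerebellar-kainate type: each animal carries epidural electrodes over left
and right motor cortex plus a third site (somatosensory in one group,
parietal in the other) and a neck-muscle EMG electrode, all sampled at
1 kHz. Day 0 is an uninjected baseline; on days 1–5 a short pre-injection
recording (10 min) is followed by a long post-injection recording
(150 min). Dystonic behavior is scored from video on a 0–4 ordinal scale
per 10-minute epoch by several independent reviewers, and active-wake
(exploratory locomotion) intervals are annotated. Every longitudinal
measure is finally expressed as a percentage of the same animal's
baseline-day value, which removes per-animal gain factors (electrode
impedance, amplifier settings) exactly: scaling a signal by `c` scales all
its band powers by `c²` but leaves the normalized percentages unchanged.

## Spectral stage

Power spectra use the Welch estimator: the signal is cut into 2 s windows
advancing by 1 s, each window is mean-detrended, Hamming-tapered and
Fourier-transformed, and the one-sided periodograms are averaged over the
windows kept by the artifact mask. The 2 s window fixes the resolution at
Δf = 0.5 Hz, which places every band edge of the scheme (0.5, 3.5, 4, 12,
13, 30, 30.5, 48, 52, 100 Hz) exactly on the grid. Scaling is spectral
density (µV²/Hz) with window-power correction, so `sum(psd) * Δf` equals
the kept-segment variance (Parseval); the package's tests hold this to
within 5% for white noise and recover the analytic `A²/2` power of a
sinusoid to within 2%.

The taper and detrend defaults are configurable (`spectral_params()`)
because the classical description of this analysis fixes only the window
and overlap; Hamming with per-segment mean removal is the default of the
standard engineering implementations and is what we adopt.

Band powers are trapezoidal integrals of the PSD over the closed band
interval. The scheme deliberately leaves 48–52 Hz uncovered: 50 Hz mains
contamination is strongly coherent across electrodes and would otherwise
dominate both low- and high-gamma summaries, so the gap acts as a
band-scheme-level notch and no time-domain notch filter is applied
anywhere. Whether per-band "power" should be the integral or the mean
density is ambiguous in common usage; we use the integral, and note that
baseline-percentage normalization makes the two conventions identical up
to the constant band width.

## Connectivity stage

For a channel pair the cross-spectrum `S_xy` is estimated with exactly the
same windows, taper, mask and scaling as the auto-spectra, and

- magnitude-squared coherence: `msc(f) = |S̄_xy|² / (S̄_xx S̄_yy)`,
- complex coherency: `C_xy(f) = S̄_xy / √(S̄_xx S̄_yy)`.

`msc` is bounded in [0, 1] up to round-off (excess beyond 1e−9 raises a
warning rather than being clipped silently) and is identically 1 when only
one segment is averaged; such degenerate estimates are flagged. The
imaginary part `Im C_xy` is the volume-conduction-robust quantity: purely
instantaneous mixing of a common source produces a real cross-spectrum, so
`Im C` stays at its estimation noise floor (which shrinks like
`1/√n_segments`) while `msc` rises. A genuinely lagged interaction at lag
τ puts phase `2πfτ` on the cross-spectrum; at a quarter period
`|Im C| = √msc`, an identity the acceptance checks verify.

Band-level summaries are arithmetic means over the bins in each band. For
the imaginary part the primary summary is `mean(|Im C|)`, because a
band-level imaginary coherence has no canonical sign convention; the
signed mean is emitted alongside so either aggregation can be inspected.

## EMG stage

EMG analysis is restricted to 1–100 Hz. The spectral descriptors are the
centroid frequency `MNF = Σ f P(f) / Σ P(f)` and the median frequency
`MDF`, the smallest frequency at which the cumulative power reaches half
the total, linearly interpolated inside the crossing bin (the standard
reading of "splits the spectrum into two halves of equal power").
Amplitude descriptors are RMS and ARV over artifact-free samples; the
power-mean inequality guarantees `RMS ≥ ARV` with equality only for
constant magnitude, and the tests assert this on random signals. Whether
the spectra should be computed on rectified EMG is not settled in this
literature; the default is the raw signal, with a `rectify` switch on
`emg_spectrum()`.

## Artifact rejection

The original screening this stage replaces is visual. The automated
surrogate rejects a whole 2 s analysis window when any screened channel's
within-window peak robust z-score — against the whole-recording median and
1.4826×MAD — exceeds 6, or when a channel is flat (range < 0.5 µV,
a disconnected-electrode signature). Only ECoG channels are screened by
default: large-amplitude EMG bursts are the physiological signal of
interest, not artifacts, and screening them would systematically delete
the most dystonic epochs. Rejection is aligned to the spectral windows so
downstream stages consume only complete windows, and it is monotone in the
threshold (lowering `z_thresh` never enlarges the kept set).

## Statistical battery

Sample-level comparisons route through a Shapiro–Wilk check at α = 0.05 to
a parametric branch (one-way ANOVA; Welch t vs control with Holm
adjustment) or a rank branch (Friedman across days within animals;
rank-sum vs control with Bonferroni adjustment). The vs-control families are deliberate, clearly
labelled approximations of Dunnett's and Dunn's procedures, whose exact
critical values require multivariate-t and studentized-range tables; the
Holm/Bonferroni versions control the family-wise error slightly
conservatively and need no special tables. Mann–Whitney comparisons use
exact enumeration when `n_x + n_y ≤ 12` with no ties (verified in the
tests against brute-force enumeration of every arrangement) and the
normal approximation with tie correction otherwise. All p-values are
two-sided; α = 0.05 throughout. Behavior–signal association uses Pearson
correlation with the two-sided t transform on n−2 df, reported together
with the least-squares slope and intercept; strata with fewer than three
paired sessions, or with zero variance on either side (e.g. every animal
scoring the ceiling on one day), are reported as undefined rather than
dropped.

## The synthetic cohort and what it does (not) show

Because raw recordings from such experiments are rarely deposited, the
package ships a generator that reproduces the *structure* of the study
with fully known ground truth: per-channel 1/f^β background (β = 1,
20 µV RMS by default) plus narrowband components realized as band-limited
Gaussian noise, a 50 Hz line sinusoid (10 µV RMS) that lands in the
band-scheme gap, cross-channel coupling with configurable band, strength
and lag, EMG as passband noise (20–90 Hz) with tonic per-day gains and
multiplicative bursts, reviewer-noise-corrupted behavior scores, active
wake laid out in 1-minute blocks hitting the per-day target fraction
exactly up to block rounding, and optional spike artifacts placed so a
known fraction of analysis windows is contaminated.

Default per-day profiles encode the qualitative trends of this model
system, chosen once as a realistic scenario: high-gamma component RMS
rising linearly to 1.5× baseline on day 5 (2.25× in power, so the
pipeline should report 225% of baseline); beta-band cortico-cortical
coupling halved in post-injection sessions; dystonia scores absent at
baseline, peaking on day 3 (mean target 3.2) and falling to a minimum on
day 5, with a within-session rise-and-fall peaking near minute 50;
post-injection activity reduced relative to baseline while pre-injection
activity creeps upward across days. All profiles are configuration, not
behavior baked into the analysis.

Two numerical choices deserve note. First, the narrowband components and
coupling filters use a 4th-order Butterworth *magnitude* response applied
in the frequency domain — zero-phase by construction and numerically
stable at any relative bandwidth, where the polynomial time-domain form of
the same filter diverges for bands as narrow as 0.5–3.5 Hz at 1 kHz.
Second, each session draws its RNG stream from a deterministic hash of
(master seed, group, animal, day, phase), so any single session can be
regenerated without generating the cohort around it, and a fixed
`cohort_spec` is bit-reproducible.

What passing the recovery tests shows: the analysis chain is unbiased and
correctly normalized for signals whose band structure, coupling and
artifacts are of the injected kind. What it does not show: robustness to
non-stationarity within sessions, electrode drift, movement artifacts with
spectral signatures inside the analysis bands, muscle contamination of
ECoG, or scorer biases correlated with signal quality — none of which the
generator emulates. Conclusions about real recordings still require the
usual visual quality control.

## Problem sizes and runtime choices

The test-suite and acceptance computations run on one CPU at reduced but
statistically adequate sizes, chosen as the package's own verification
conditions: 300 s signals for the spectral and coherence closed forms
(≈300 averaged segments, putting the coherence noise floor near 0.01),
a reduced recovery cohort of 2 groups × 3 animals × 6 days × 2 phases with
60 s pre and 300 s post sessions, and 2000 replicates per null for the
type-I-error calibration (standard error ≈0.5 percentage points at the
nominal 5%).

## File formats

CSV signal files are lossless (`time_s` column plus one column per
channel) but carry no sampling rate, which must come from the manifest.
EDF files quantize each channel to 16 bits over its own symmetric physical
range (worst-case error full-scale/2¹⁵, ≈0.003% of full scale); the true
sample count is stowed in the reserved header field so the zero-padded
final record round-trips exactly. Manifests, ground truth and resolved
run configurations are JSON; every analysis table is tidy CSV with the
session key (`animal_id`, `group`, `day`, `phase`) as leading columns.
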