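---
title: "Multilevel sleep-EEG analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel sleep-EEG analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnarch)
```

somnarch analyzes overnight multichannel sleep EEG at four levels:
spectral (power spectral density, aperiodic slope, band ratios), nonlinear
(multiscale sample entropy), distributional (robust percentiles) and
event-level (sleep spindles and slow oscillations), plus whole-night macro
architecture from the hypnogram and agreement statistics for multi-scorer
and multi-device designs. Because clinical recordings are rarely sharable,
the package ships a seeded synthetic-night generator that reproduces the
statistical structure these analyses assume, so every stage of the
pipeline is testable end to end. This vignette documents the models, the
parameters that matter, and the design decisions that were genuinely open.

## The synthetic night

A night is a 30-s-epoch hypnogram over the stages W, N1, N2, N3 and REM,
plus one signal per montage channel at 500 Hz (the conventional PSG
sampling rate; configurable).

**Hypnogram.** `generate_hypnogram()` lays stages out as alternating
NREM/REM cycles (default period 180 epochs = 90 min) starting from wake.
Stage totals are fixed first by largest-remainder rounding of the
requested proportions, then partitioned across cycles with seeded jitter.
This deterministic-template design, rather than a Markov chain, was chosen
so realized stage fractions match the request exactly up to rounding —
important because several tests condition on stage-time denominators. The
default proportions (N2 50%, N3 20%, REM 25%, remainder W/N1) follow the
healthy-adult guidance ranges.

**Background signal.** Each epoch's background is `1/f^alpha` noise
synthesized by spectral shaping: white Gaussian noise is transformed to
the frequency domain, amplitudes multiplied by `f^(-alpha/2)`, transformed
back, and rescaled to the exact target RMS. This gives an exact target
exponent in O(N log N) time. Per-stage defaults are field-plausible rather
than fitted to any particular cohort (no public reference values exist for
the device montage emulated here): the aperiodic exponent steepens with
NREM depth (W 1.2, N1 1.5, N2 2.0, N3 2.6) and relaxes in REM (1.6), RMS
amplitude grows from roughly 15 uV in wake to 50 uV in N3, wake carries a
10 Hz posterior-alpha oscillation, and N1/REM carry weak theta.

**Events.** Ground-truth spindles are Hann-windowed sinusoids (smooth
onset and offset, so duration thresholds can be probed near their
boundaries); slow oscillations are a spliced pair of half-sine waves
(negative then positive), so each detection criterion can be violated
independently. Default rates are 3 spindles/min in N2, 1/min in N3, and
5 SOs/min in N3. Spindle peak amplitude defaults to 25 uV; SO half-waves
to -80/+50 uV. All randomness descends from one integer seed through a
deterministic splitter, so identical seeds give bit-identical nights.

What the generator does *not* emulate: EMG morphology, ocular or motion
artifacts, electrode drift, arousals, or stage-transition
microstructure. Tests passing on this generator therefore demonstrate
algorithmic correctness and calibration — not robustness to artifacts in
clinical recordings.

## Preprocessing

EEG and EOG channels are bandpassed 0.3-35 Hz and EMG 10-100 Hz with a
4th-order Butterworth applied forward-backward (zero phase, effective 8th
order). The bandpass is realized as a high-pass/low-pass cascade because a
direct transfer-function bandpass with a corner at 0.3 Hz of 500 Hz is
numerically fragile in polynomial form. A 10 Hz tone passes within 5% and
a 0.05 Hz drift is attenuated by far more than 20 dB. Signals are cut
into 30-s epochs aligned to the hypnogram; a partial trailing epoch is
dropped, intervals are half-open, and sample indexing is 0-based in
seconds.

EDF input/output is implemented directly against the format's fixed
header layout with 16-bit scaling, so roundtrip error is bounded by
`physical_range / 2^16` per sample. Mixed per-channel sampling rates are
rejected rather than resampled.

## Spectral analysis

`welch_psd()` estimates the PSD per epoch with 4-s Hann windows and 2-s
overlap after per-epoch mean removal (constant detrend, suppressing DC
leakage into the slow band), averages across the epochs of a stage, and
reports the grid 0.5-30 Hz in steps of 0.5 Hz (60 bins).

A 4-s window gives native 0.25 Hz resolution, i.e. two native bins per
output bin. The output bin at frequency `f` is the *centered mean* of the
native bins in `(f - 0.25, f + 0.25]`. Two alternatives were considered
and rejected on oracle measurements. Plain decimation (keeping only
native bins at multiples of 0.5 Hz) violates Parseval for narrowband
signals: a unit 10 Hz tone integrates to 2/3 uV^2 instead of the true
A^2/2 = 0.5 uV^2. A left-aligned mean over `(f - 0.5, f]` preserves
Parseval but pulls the heavily leakage-contaminated 0.25 Hz native bin
into the first output bin, which biases power-law slope fits on steep
spectra by up to -0.5 at alpha = 3. The centered mean preserves band
integrals (the tone oracle gives exactly 0.5 uV^2) and recovers
generative exponents alpha in {1, 2, 3} within +/-0.04.

`spectral_slope()` fits ordinary least squares of log10 power on log10
frequency over all 60 bins, the standard description of the aperiodic
1/f component; on an exact power law the fit is exact with R^2 = 1.
Non-positive bins are excluded with a warning. `relative_band_power()`
integrates the six classical bands — slow 0.5-1, delta 1-4, theta 4-8,
alpha 8-12, sigma 12-15, beta 15-30 Hz — with half-open edges except the
top of beta, so the bands partition the grid and relative powers sum to
one exactly.

**Slowing index.** The EEG/EOG slowing index is the ratio of low
(delta + theta) to high (alpha + beta) relative power with a +/-3 SD
outlier-masking function `f` applied at three nested levels: to each band
series across epochs, to the numerator and denominator sums, and to the
final ratio; masked values propagate as missing and the index is the mean
of surviving epoch ratios. The SD is the sample SD (denominator n-1)
within channel and stage. Whether the index should pool epochs across the
whole night or within stage is not settled usage; the default here is
per stage (configurable simply by which epochs are passed in), which
keeps the index interpretable as stage physiology. Groups with fewer than
3 epochs report a missing index, since the masking SD is undefined.

## Multiscale entropy

Sample entropy SampEn(m, r) = -ln(A/B) counts m-template matches (B) and
their m+1 extensions (A) under Chebyshev distance with self-matches
excluded, with m = 2 and r = 0.15 x SD. The matching core is implemented
in C++ (quadratic in series length) and is tested to agree with an
independent brute-force R implementation to 1e-12; a test also covers
m = 3 and strongly autocorrelated input.

Multiscale entropy coarse-grains the series by non-overlapping means at
scales 1, 3, 5, 7 and 9 and computes SampEn at each. The tolerance
r x SD is computed **once from the original series** and reused at all
scales. This is the convention that preserves the diagnostic crossover:
white noise loses entropy monotonically with scale while 1/f noise does
not, so the 1/f curve lies above white noise at coarse scales. Had the
tolerance been recomputed per scale, the crossover would largely vanish.

Whether stage-level entropy should be computed on the concatenated
within-stage signal or per epoch and averaged is ambiguous in common
usage; `stage_entropy()` concatenates (per-epoch series of 15,000 samples
shrink to ~1,600 points at scale 9, marginal for m = 2 template
statistics) and records the choice in its output. Because SampEn is
quadratic in length, the pipeline caps each series at its first 15,000
samples by default — a sample-size choice that keeps template counts in
the tens of millions while bounding compute; the cap is flagged in the
`capped` column.

## Percentile features

Signals are standardized robustly — centered at the median, scaled by
IQR/1.349, where 1.349 is the IQR of a standard normal — and the twelve
percentiles P01 through P99 are read off with linear interpolation
between order statistics (the common default; no rule is canonical).
This makes the features exactly invariant to affine amplitude changes
(amplifier gain, reference shifts), which is what makes them comparable
across devices. Degenerate inputs (zero IQR) raise an error rather than
return infinities.

## Event detection

**Spindles.** The detector follows the wavelet scheme standard in the
field: bandpass fc +/- 2 Hz, complex Morlet magnitude at the target
frequency (fc = 11 Hz for slow, 15 Hz for fast spindles), moving-average
smoothing over 0.1 s, normalization by the mean smoothed magnitude over
all N2+N3 epochs, then thresholding: an event is a maximal run of at
least 0.5 s above 2x the mean containing a sub-run of at least 0.3 s
above 4.5x. Event boundaries come from the 2x run. Events closer than
0.5 s are merged and events longer than 3 s discarded (merge/cap values
follow common detector practice and are config-exposed). Only events
whose peak falls in a target-stage epoch are kept.

Two implementation details matter. First, the fc +/- 2 Hz pre-filter is
a passband-flat linear-phase FIR rather than a Butterworth: zero-phase
Butterworth corners at exactly fc +/- 2 attenuate an in-band burst at fc
by roughly a third, which distorts the amplitude criteria for no benefit
— the wavelet supplies the frequency selectivity. Second, the Morlet
length is parameterized in cycles (default 7 at fc, giving a time
resolution of about 0.1 s at 11 Hz); the cycles parameter trades temporal
against frequency resolution and is exposed in `spindle_params()`.

The thresholds imply a detectability floor worth stating explicitly. A
Hann-enveloped spindle of duration `d` whose peak reaches `k` times the
normalization mean stays above the 4.5x core threshold for
`d * (1 - acos(1 - 9/k) / pi)` seconds, so at k = 5 no spindle of 1.5 s
or less can satisfy the 0.3 s core criterion, while at k >= 9 spindles
down to 0.6 s can. Injection-recovery fixtures therefore use clearly
formed spindles (8-16x the sigma-band background RMS, the regime of
visually unambiguous spindles); there the detector achieves >= 0.9
sensitivity with mean onset error near 0.1 s and essentially zero false
detections on event-free 1/f noise.

**Slow oscillations.** The signal is bandpassed 0.5-4 Hz with a
linear-phase windowed-sinc FIR (order set by a 0.5 Hz transition width,
group delay compensated exactly). On the filtered trace, a candidate is a
negative half-wave between a downward and the next upward zero crossing,
immediately followed by a positive half-wave. It is accepted iff all four
criteria hold: negative peak <= -40 uV, peak-to-peak >= 75 uV, negative
duration 0.3-1.5 s, positive duration in (0, 1] s. The criteria are
evaluated on the filtered signal — the filtering step defines the
morphology the thresholds refer to. One consequence is easy to
underestimate: removing content below 0.5 Hz strips the large
quasi-DC component of a lone half-wave, so an injected -60 uV half-wave
of 0.8 s retains only about -37 uV after *any* 0.5-4 Hz filter
(an ideal brickwall agrees with the FIR within ~1.5 uV). Detection
fixtures are therefore specified in filtered-domain terms; the
generator's -80/+50 uV default wave passes all four criteria after
filtering with comfortable margins.

**Features and coupling.** `spindle_features()` and `so_features()`
summarize an event set in the conventional panel: density/rate per minute
of the detector's target stage, durations, within-event frequency both by
zero-crossing count (FRQ) and spectral peak (FFT), FWHM of the smoothed
wavelet magnitude around the peak, oscillation counts, and for SOs the
median half-wave amplitudes, durations, peak-to-peak and slopes from/to
the negative peak (uV/s). The spindle count variants N01/N02/N-in-N2 are
reported as counts under the extended-duration rule, the core-duration
rule, and stage-N2 restriction respectively — the panel names are
conventional but their exact definitions are not standardized, so these
interpretations are documented here and in the function help. A spindle
is *coupled* when its interval intersects an SO interval (counted once
per spindle); TRANS counts coupled spindles whose peak falls inside the
SO's positive half-wave, the phase window associated with spindle
generation. `time_locked_average()` averages signal windows centered on
event anchors, excluding (and counting) events whose window would cross
the recording edge.

## Macro architecture

The hypnogram metrics use explicit, config-exposed definitions, since the
metric names are standard but their operationalizations vary across labs:
sleep onset is the first non-wake epoch; TIB is the full recording span;
TST is total sleep time; WASO counts wake between onset and the last
sleep epoch (trailing wake excluded); SLP_EFF = 100 TST/TIB;
SLP_MA_EFF = 100 TST / (onset through last sleep epoch); REM latency runs
from sleep onset to the first REM epoch; persistent-sleep latency from
recording start to the first run of >= 10 uninterrupted sleep epochs
(5 min). A NREM cycle is a NREM period of >= 30 epochs (15 min)
terminated by a REM period of >= 10 epochs, the REM minimum being waived
for the first cycle; NREMC reports the mean cycle duration and count.
These definitions are verified against an independent scan-based oracle
on 1,000 random hypnograms.

## Agreement statistics

Cohen's kappa is unweighted over the five stages with marginal-product
chance agreement; the 5x5 confusion matrix (and a row-normalized display
version) is attached, unscored epochs are dropped pairwise with the
effective n reported, and the p-value uses the large-sample null
variance. ICC(3,1) — two-way mixed model, consistency, single measurement
— is computed from the ANOVA mean squares,
`(MS_rows - MS_error) / (MS_rows + (k-1) MS_error)`, with the standard
F-based 95% interval, and is insensitive to fixed rater offsets by
construction; interpretation bands are poor < 0.5 <= moderate < 0.75 <=
good < 0.9 <= excellent. Mann-Whitney U and the pooled-variance t-test
delegate to the stats package (exact small-sample enumeration for
tie-free U, tie-corrected normal approximation otherwise); one-way
repeated-measures ANOVA is fitted with `aov()` using a subject error
stratum. Every statistic is tested against an independent closed form,
hand computation or exhaustive enumeration; simulated paired devices with
true ICC 0.9 are recovered within 0.004 on average over 500 replicates
of 50 subjects. No multiple-testing correction is applied; per-test
p-values are reported as-is.

## Numerical and degenerate-input policy

- All intervals are half-open `[onset, offset)` in seconds; epoch 0
  starts at t = 0.
- Filters: zero-phase Butterworth (HP+LP cascade) for broadband
  class-specific filtering; linear-phase FIR with exact integer delay
  compensation wherever event morphology feeds amplitude criteria.
- Convolutions run via FFT with power-of-two padding; results are
  shift-equivariant away from the recording edges to within one sample.
- Constant series yield missing sample entropy with a reason code; zero
  template matches yield missing, not infinite, entropy. Zero-variance
  rating tables yield missing ICC; a degenerate kappa (both raters
  constant and equal) is missing, not 1. Zero-denominator slowing-index
  epochs become missing and are excluded by the masking chain.
- ICC estimates are clamped at 1 against floating-point cancellation;
  repeated-measures F is 0 when the condition mean square is numerically
  zero.

## Problem sizes used by the test suite

The suite validates calibration at deliberately moderate sizes chosen as
standard desk-scale experiments: injection-recovery uses two 30-min
synthetic N2 records (60 spindles) and 10 min of event-free noise; slope
recovery uses 300-s records, 10 seeds per exponent; entropy ordering uses
20 paired 15,000-sample series; ICC recovery uses 500 replicates of 50
subjects; the macro oracle runs 1,000 random hypnograms; and the
end-to-end determinism check runs a 3-subject, 6-epoch, 2-channel
configuration twice and compares outputs byte for byte.

## Known limitations

- The generator's stage profiles are plausible, not fitted; absolute
  feature values (e.g. entropy magnitudes, band-power fractions) should
  not be read as normative.
- Spindle detection below ~9x background sigma-band level is physically
  limited by the 4.5x/0.3 s core criterion (see the detectability floor
  above); weak spindles are missed by design of the thresholds.
- The SO amplitude criteria apply to the 0.5-4 Hz filtered trace;
  unfiltered amplitudes are systematically deeper than their filtered
  counterparts.
- Agreement machinery covers two raters (pairwise kappa) and complete
  tables only; there is no chance-model for >2 raters.
- The Welch estimator is the plain windowed-segment average; no
  multitaper or log-frequency-averaged variants are provided.
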