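---
title: "Methods and design notes for hrvkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for hrvkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvkit)
```

This vignette documents the models and procedures hrvkit implements, the
parameters that matter and their defaults, the numerical decisions taken
where conventions genuinely diverge, and what the synthetic-data tests
do and do not establish about real recordings.

## The signal model

An RR-interval series (tachogram) is an ordered sequence of intervals in
ms. The package anchors each interval at the time it *ends*: the
cumulative time axis is `cumsum(values) / 1000` seconds, with the record
starting at 0. All analyses consume this container (`rri_series`); all
interval arithmetic is in ms and all time axes in seconds.

HRV indices assume the series contains only sinus ("normal-to-normal")
beats. Ectopic beats and detection artifacts produce outlier intervals
that inflate every variability measure, which is why filtering precedes
analysis.

## R-peak detection

The detector is deliberately simple and transparent: band-pass, first
derivative, fixed threshold.

* **Passband 5–200 Hz, Butterworth order 4.** 5 Hz removes baseline
  wander; 200 Hz removes high-frequency noise while keeping the QRS
  rise. The filter is applied forward and backward (`signal::filtfilt`)
  so it is zero-phase: causal filtering would delay the R-wave by a
  filter-dependent lag and bias every interval. An upper edge at or
  above the Nyquist frequency is rejected with an error rather than
  clipped — silently changing the passband would silently change the
  detection.
* **Candidate rule.** A candidate is a sample where the first difference
  of the filtered signal turns from positive to non-positive (a local
  maximum); it is accepted when the **raw** ECG there exceeds the fixed
  threshold. The amplitude test uses the raw trace because filtering
  attenuates amplitudes unevenly across morphologies, making a
  user-supplied absolute threshold harder to interpret.
* **Refractory window 200 ms.** The derivative rule alone fires on any
  ripple above threshold. Since no physiological RR interval is shorter
  than about 200 ms, only the largest-amplitude candidate within any
  200 ms span is kept. Manual edits (`edit_peaks`) override the
  algorithm; the refractory rule is *not* re-applied to user additions.

A fixed absolute threshold is a known weakness on drifting or
low-amplitude recordings — that is what the editing API is for. No
adaptive thresholding is attempted.

## Artifact filtering

* **Moving average / moving median** use centred windows with edge
  truncation, preserving series length. The median window must be odd so
  the centre is well defined.
* **Quotient filter.** A beat is flagged when its ratio with *either*
  neighbour is ≥ 1.2 or ≤ 0.8 (inclusive thresholds; endpoints judged
  against their single neighbour). All flags are computed on the
  original series and removals applied at once. The underlying pairwise
  rule does not say which member of a violating pair to drop; removing
  any beat that violates against either neighbour removes the ectopic
  itself (a short interval flags against both neighbours) and is
  deterministic. The filter is single-pass by design — removal can
  create new adjacencies that a second pass would flag, and iterating
  the rule can cascade through a noisy series. A two-beat series whose
  ratio violates the rule loses both beats; the empty result is
  representable (the container permits length 0, and downstream
  operations enforce their own minimum lengths).

## Spectral pipeline

`frequency_analysis()` chains four stages on one 4 Hz grid:

1. **Cubic-spline resampling** (`interpolate_resample`). Fourier and AR
   estimators need even sampling; the spline interpolates interval
   amplitude against the cumulative beat-time axis and evaluates it from
   the first to the last beat onset at 1/fs steps. 4 Hz is the
   conventional rate for human tachograms (oscillations of interest are
   below 0.4 Hz). At least 4 beats are required.
2. **Polynomial detrending** (`detrend_polynomial`), default linear,
   any degree up to n − 1. Slow drift otherwise leaks into the VLF band.
   Detrending operates on the resampled grid so the whole spectral
   pipeline shares one time base.
3. **PSD estimation**, Welch or Burg (below).
4. **Band integration** (`band_powers`).

### Welch averaged periodogram

`P = floor((N − D) / S) + 1` segments of length `D` (default 256
samples, i.e. 64 s at 4 Hz) shifted by `S` (default 128, 50 % overlap).
Each segment is mean-removed, windowed, zero-padded to `padded_len`, and
its one-sided periodogram computed; the estimate is the plain arithmetic
mean of the P periodograms. Normalisation divides by
`fs * sum(w^2)` (window power compensation) and doubles interior bins
but not DC or Nyquist, so the trapezoidal integral of a
rectangular-window estimate recovers the segment variance. Per-segment
mean removal is not universal in Welch implementations; it is applied
here because a 900 ms mean level would otherwise dwarf every
physiological component via DC leakage.

Windows: Hann (default), Hamming, Blackman, triangular, rectangular,
Kaiser with shape β = 8.6 (Blackman-like sidelobe suppression; the
shape parameter has to be fixed somewhere and 8.6 is the common
high-attenuation choice). Zero-padding refines the frequency grid
without adding information; band powers move by well under 1 % on smooth
spectra (tested).

### Burg autoregressive estimate

The Burg recursion chooses each reflection coefficient to minimise the
summed forward and backward prediction-error power, updating the monic
polynomial `A(z) = 1 + a_1 z^{-1} + … + a_p z^{-p}` by the Levinson
step. The one-sided density is
`2 σ² / (fs |A(e^{-i2πf/fs})|²)` with σ² the final prediction-error
power, evaluated on a grid of `padded_len` points (default 1024). The
series mean is removed before fitting. Default order 16 trades
resolution against variance for resting tachograms of a few hundred
samples; the order must be below the series length. Doubling follows
the same interior-bins-only convention as Welch so band integrals from
the two methods are directly comparable. A zero-variance input yields a
flat zero PSD with a warning rather than an error.

The implementation is cross-checked in the test suite against
`stats::ar.burg` (coefficients agree to 10⁻³ on an 8192-sample AR(2)
simulation) — the library routine serves as an independent oracle only.

### Band powers

Bands default to VLF 0–0.04, LF 0.04–0.15, HF 0.15–0.4 Hz, all
adjustable. A VLF lower bound of 0.003 Hz is sometimes used; with the
default linear detrend the content below 0.003 Hz is largely removed
anyway, and 0 keeps TP equal to the full integral — users who want the
0.003 Hz convention pass `edges = c(0.003, 0.04, 0.15, 0.4)`. Each band
power is the trapezoidal integral of the density with the density
linearly interpolated *at* the band edges, so contiguous bands tile
exactly: VLF + LF + HF = TP to floating precision, and
LFnu + HFnu = 100 whenever TP > VLF. Degenerate cases return `NA`
markers rather than infinities: LF/HF when HF = 0, normalized units when
TP ≤ VLF. Band powers are reported in ms² (the integral of a ms²/Hz
density over Hz).

## Time-domain conventions

Three points where published conventions diverge are settled as
follows, each with the alternative reachable by argument:

* **pNN50 denominator.** `nn50_pnn50()` divides by the total interval
  count N by default; the more common N − 1 (number of successive
  differences) variant is available via `denominator = "n-1"`. The
  N-denominator value is never larger (tested property).
* **Mean HR.** `mean_indices()` averages the instantaneous beat-wise
  rate 60000/RRi by default; `hr_method = "overall"` gives
  60000/mean(RRi). The two differ on any non-constant series
  (`c(500, 1000)` → 90 vs 80 bpm).
* **Poincaré SD1.** SD1 is computed as SDSD/√2 and SD2 as
  √(2 SDNN² − SDSD²/2). These forms make SD1² + SD2² = 2 SDNN² an exact
  algebraic identity, which the tests assert; a printed variant that
  defines SD1 through SD2 circularly is not representable and is treated
  as a transcription slip. The SD2 radicand can only go negative through
  floating rounding and is clamped at 0.

SDNN, SDSD and RMSSD all use N − 1 denominators over their respective
difference counts. NN50 uses the strict inequality |ΔRRi| > 50 ms, so a
difference of exactly 50 ms does not count.

## Non-stationary engines

* **Time-varying indices** window the beat-time axis in *seconds*
  (default 30 s, no overlap): windows start at multiples of
  (segment − overlap), an interval belongs to the window containing its
  end time, and windows are half-open on the right except the final one,
  which is closed so the beat ending exactly at the record end is not
  orphaned. A trailing incomplete window is dropped — partial-window
  indices are biased low and would masquerade as a terminal HRV change.
  Windows with fewer than 2 intervals yield `NA` markers. With the
  window set to the record duration the single window reproduces the
  stationary indices exactly (tested).
* **The time–frequency map** segments the *resampled grid* in samples,
  mirroring the Welch configuration, and keeps each sub-segment's PSD as
  a row of a time × frequency matrix (times are segment centres). By
  construction the row mean equals the Welch estimate of identical
  configuration — the test suite asserts this to 10⁻⁹, and it pins the
  per-segment normalisation to the averaged estimator's. Per-segment
  processing beyond mean removal is deliberately not applied: one global
  detrend, then identical treatment of every segment.

The two engines use different segmentation units (seconds vs samples)
because they operate on different axes — beats are irregular in time,
the resampled grid is not. The command-line interface exposes each in
its native unit.

## Synthetic generators: what they do and do not establish

The generators produce the structures the analyses assume, with analytic
ground truth:

* `make_tachogram()` builds beats iteratively — the next beat follows
  the previous by the current RR value, where RRi(t) is a mean plus
  LF/HF sinusoids, a polynomial trend, and white noise. Each tone of
  amplitude A contributes A²/2 ms² to its band. This is amplitude
  modulation at the accumulated beat time, a simplification of true
  cardiac pulse-frequency modulation; at the modulation depths used
  (tones ≤ 30 ms on a 900 ms mean, < 5 %) the distinction is negligible
  for band-power ground truth, and the sample variance of a long
  two-tone record matches Σ A²/2 within 5 % (tested at 600 s). Tone
  frequencies are restricted below 0.5 Hz, comfortably under the 2 Hz
  Nyquist limit of 4 Hz resampling.
* `make_ecg()` plants Gaussian bumps (default σ = 10 ms) at the sample
  nearest each beat time, so the clean-signal maximum sits exactly on
  the planted index. Beats closer than 3σ are rejected — merged bumps
  would have no well-defined ground truth. This is not a PQRST
  morphology: detection results on it bound the detector's behaviour on
  clean, R-dominated signals only.
* `make_ar_process()` simulates a stationarity-checked AR recursion
  with a 500-sample burn-in (discarding the transient from the zero
  initial state).
* `make_exercise_tachogram()` emulates an incremental test: resting
  phase, a work ramp over which mean RR falls linearly while the
  oscillation envelope decays exponentially (vagal withdrawal), and a
  recovery in which mean RR returns on the fast ~40 s time constant of
  heart-rate recovery while the envelope recovers on the much slower
  ~150 s time constant of vagal reactivation. The separation is the
  physiologically documented pattern — HRV lags heart rate in recovery —
  and it matters for interpretation: immediately after exercise the
  rapidly changing mean leaks low-frequency power through the single
  global linear detrend, dominating per-segment total power for roughly
  the first 90 s of recovery. Assessments of the recovery trend in the
  test suite therefore start after that transient clears; the ramp
  phase needs no such exclusion. This leakage is a property of global
  detrending on nonstationary records, not of the generator; analysts
  of real post-exercise data face exactly the same artifact.

All generators take a `seed` and restore the caller's RNG state; the
same seed reproduces the output bit for bit.

What passing these tests does **not** show: robustness to real ECG
morphology (P/T waves, baseline drift, electrode artifacts), to missed
or spurious beats interacting with resampling, or to respiratory
frequency drifting across the LF/HF boundary. The generators contain
none of those.

## Problem sizes and tolerances in the test suite

Simulation sizes were chosen so the suite runs in well under a minute
while keeping statistical checks comfortably away from their thresholds:
1000 random series (lengths 10–150) for the brute-force time-domain
oracle at 10⁻¹² relative; 100 white-noise signals of 1024 samples for
the Parseval check at 2 % — at this length the trapezoid rule's halved
Nyquist bin, a χ²₁ quantity, stays well inside the band for any draw,
whereas at length 128 its fluctuations alone can exceed 2 %; an
8192-sample AR(2) realisation for Burg recovery within ±0.05; 100–200
planted beats for detection recall. Exact identities (segment-count
arithmetic, Welch-vs-row-mean, band tiling, SD1/SD2) are asserted at
10⁻⁹ or tighter.

## Known limitations

* No adaptive QRS detection; heavily drifting or low-SNR ECGs need
  manual threshold choice and peak editing.
* Uneven sampling is handled only via spline resampling — no
  Lomb–Scargle periodogram for gap-ridden series.
* The quotient filter removes beats rather than interpolating
  replacements, shortening the series and its time axis; on
  artifact-dense records this distorts the spectral time base.
* Vendor binary formats are not read; inputs are plain text and Polar
  HRM.
* Time–frequency output is a matrix plus per-segment band table;
  surface rendering is left to the user's plotting tools.
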