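# hrvkit

Heart rate variability (HRV) analysis for R: from raw ECG or RR-interval
(tachogram) data to the classical stationary time- and frequency-domain
indices, plus two engines for non-stationary records — time-varying
windowed indices and short-time time–frequency band-power maps.

HRV, the beat-to-beat variation of RR intervals, is a non-invasive marker
of cardiac autonomic modulation: respiratory-coupled high-frequency
oscillations reflect parasympathetic activity, lower-frequency
oscillations mix sympathetic and other regulatory influences. Stationary
indices summarise a resting recording with one number each; during
orthostatic stress or exercise the signal is non-stationary and the
windowed/time–frequency engines track how variability evolves. The
package is aimed at physiologists and methods researchers who want every
step — filtering, detrending, resampling, spectral estimation,
integration — explicit, scriptable and tested.

## What it computes

**R-peak detection.** The ECG is band-pass filtered (zero-phase
Butterworth, default 5–200 Hz); a peak is called where the first
derivative of the filtered signal crosses from positive to non-positive
and the raw ECG exceeds a fixed threshold; a 200 ms refractory window
keeps only the largest candidate per QRS. Peaks can be added/removed
programmatically (`edit_peaks`) and converted to RR intervals.

**Artifact filtering.** Moving average, moving median, and the quotient
filter, which removes any beat whose ratio with a neighbour satisfies
RRi\_n / RRi\_n±1 ≥ 1.2 or ≤ 0.8 (a 20 % beat-to-beat jump), flags
computed in a single pass.

**Time domain** (ms series of length N):

- SDNN = √( Σ (RRi\_j − mean)² / (N−1) )
- RMSSD = √( Σ (RRi\_{j+1} − RRi\_j)² / (N−1) )
- SD1 = SDSD/√2, SD2 = √(2·SDNN² − SDSD²/2) (Poincaré descriptors,
  satisfying SD1² + SD2² = 2·SDNN²)
- NN50 (count of successive differences > 50 ms), pNN50 = NN50/N·100
- mean RRi, mean instantaneous HR, mean successive difference

**Frequency domain.** The tachogram is cubic-spline resampled (default
4 Hz), polynomially detrended (default linear), and its one-sided PSD is
estimated either by Welch's averaged periodogram — P = ⌊(N−D)/S⌋ + 1
segments of length D (default 256) shifted by S (default 128), mean
removed, windowed (Hann default), zero-padded, averaged — or by a Burg
autoregressive model (default order 16) evaluated through its frequency
response. Band powers are trapezoidal integrals of the density over
VLF 0–0.04, LF 0.04–0.15, HF 0.15–0.4 Hz (edges adjustable), with
LFnu = LF/(TP − VLF)·100, HFnu likewise, and LF/HF.

**Non-stationary analysis.** `time_varying_indices()` computes every
time-domain index in sliding windows (default 30 s, no overlap) over the
beat-time axis; `time_frequency_map()` keeps each Welch sub-segment's PSD
(or a per-segment Burg fit) as a time × frequency matrix with per-segment
band powers — averaging its rows reproduces the Welch estimate exactly.

**Synthetic ground truth.** Seeded generators build tachograms from
LF/HF tones (+ trend, noise, planted ectopics), Gaussian-bump ECGs with
known peak positions, stationary AR processes, and an exercise-like
ramp-and-recovery record; every generator returns the analytic truth it
planted, and the test suite leans on them throughout.

## Worked example

```r
library(hrvkit)

tg <- make_tachogram(300, mean_rri_ms = 900,
                     tones = data.frame(freq_hz = c(0.1, 0.25),
                                        amp_ms  = c(30, 20)),
                     noise_sd_ms = 2, seed = 42)
tg$rri
#> <rri_series> 333 intervals, 299.5 s [synthetic tachogram]
#>   mean RRi: 899.337 ms

round(time_domain_indices(tg$rri), 3)
#>   n_intervals mean_rri mean_hr mean_succ_diff   sdnn rmssd   sdsd    sd1    sd2
#> 1         333  899.337   66.77         -0.132 25.605 22.01 22.043 15.586 32.684
#>   nn50 pnn50
#> 1    0     0

fa <- frequency_analysis(tg$rri, method = "welch")
fa$bands
#> <band_powers> TP=650.59 VLF=0.94 LF=448.84 HF=200.81 ms^2 | LF/HF=2.24 LFnu=69.09 HFnu=30.91
```

The two planted tones carry analytic powers A²/2 = 450 ms² (0.1 Hz, LF)
and 200 ms² (0.25 Hz, HF); the estimated LF and HF integrals land on
both, the 2 ms beat noise contributes the small remainder, and LF/HF
reflects the 450/200 ratio. On a 300 s record resampled at 4 Hz the
default 256-sample segments give 8 averaged periodograms.

The same pipelines are available from the shell via the thin wrapper
installed at `exec/hrv`:

```sh
hrv time-domain rri.txt -o indices.csv
hrv freq-domain --method welch --segment 256 --overlap 128 rri.txt -o bands.csv
hrv time-varying --segment 30 rri.txt -o tv.csv
```

Input formats: plain text (one RR interval or one ECG sample per line,
`#` comments skipped) and Polar `.hrm` files; results are written as CSV.

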