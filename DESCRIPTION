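Package: hrvkit
Title: Heart Rate Variability Analysis for Stationary and Non-Stationary RR
    Interval Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for heart rate variability (HRV) analysis from ECG or RR
    interval (tachogram) data: derivative-based R-peak detection with a
    zero-phase Butterworth pre-filter, artifact filtering (moving average,
    moving median, quotient filter), classical time-domain indices (SDNN,
    RMSSD, SDSD, Poincare SD1/SD2, NN50/pNN50), frequency-domain indices
    from Welch averaged-periodogram or Burg autoregressive spectral
    estimates with trapezoidal band integration (VLF/LF/HF/TP, normalized
    units, LF/HF), and non-stationary analysis via time-varying windowed
    indices and short-time time-frequency band-power maps. Includes seeded
    synthetic ECG and tachogram generators with analytic ground truth, text
    and Polar HRM readers, CSV export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
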