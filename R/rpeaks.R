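#' Zero-phase Butterworth band-pass filter for ECG
#'
#' Removes baseline wander and high-frequency noise ahead of R-peak
#' detection. The filter is applied forward and backward
#' ([signal::filtfilt]) so it has zero phase: peak latencies are preserved,
#' which the derivative-based detector relies on.
#'
#' @param ecg An [ecg_record].
#' @param low Lower passband edge, Hz.
#' @param high Upper passband edge, Hz. Must be below `fs / 2`; for low
#'   sampling rates the 200 Hz default is infeasible and is rejected rather
#'   than silently clipped.
#' @param order Butterworth order per band edge (default 4).
#' @return A filtered [ecg_record] of the same length and `fs`.
#' @export
bandpass_ecg <- function(ecg, low = 5, high = 200, order = 4) {
  stopifnot(inherits(ecg, "ecg_record"))
  fs <- ecg$fs
  if (!(is.finite(low) && is.finite(high) && low > 0 && high > low))
    stop_hrv("passband edges must satisfy 0 < low < high",
             class = "hrvkit_validation")
  if (high >= fs / 2)
    stop_hrv(paste0("upper passband edge %g Hz is not below the Nyquist ",
                    "frequency %g Hz; lower the upper edge"),
             high, fs / 2, class = "hrvkit_validation")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  ecg_record(signal::filtfilt(bf, ecg$samples), fs = fs,
             start_time = ecg$start_time)
}

peak_annotation <- function(peak_indices, fs, n_samples,
                            threshold_used = NA_real_,
                            passband_used = c(NA_real_, NA_real_)) {
  peak_indices <- sort(unique(as.integer(peak_indices)))
  structure(list(peak_indices = peak_indices, fs = fs,
                 n_samples = as.integer(n_samples),
                 threshold_used = threshold_used,
                 passband_used = passband_used),
            class = "peak_annotation")
}

#' @export
print.peak_annotation <- function(x, ...) {
  cat(sprintf("<peak_annotation> %d peaks @ %g Hz (threshold %g)\n",
              length(x$peak_indices), x$fs, x$threshold_used))
  invisible(x)
}

#' Detect R-peaks by derivative zero crossing and fixed threshold
#'
#' The ECG is band-pass filtered ([bandpass_ecg]); a candidate peak is any
#' sample where the first difference of the filtered signal turns from
#' positive to non-positive. A candidate is accepted when the *raw* ECG
#' there exceeds the fixed `threshold`. Within any refractory window
#' (default 200 ms, a physiological minimum RR) only the largest-amplitude
#' candidate is kept, which suppresses double detections on a single QRS
#' complex.
#'
#' @param ecg An [ecg_record] (raw, unfiltered).
#' @param threshold Fixed amplitude threshold in the raw signal's units.
#' @param low,high,order Passband configuration passed to [bandpass_ecg].
#' @param refractory_s Minimum peak spacing, seconds.
#' @return A `peak_annotation` with sorted sample indices (1-based).
#'   An empty annotation — threshold above the signal maximum, or a flat
#'   record — is a valid result, not an error.
#' @export
detect_rpeaks <- function(ecg, threshold, low = 5, high = 200, order = 4,
                          refractory_s = 0.2) {
  stopifnot(inherits(ecg, "ecg_record"))
  if (!is.finite(threshold))
    stop_hrv("threshold must be finite", class = "hrvkit_validation")
  n <- length(ecg$samples)
  if (n < 6 * order)
    stop_hrv("ECG too short to filter: %d samples (need >= %d)",
             n, 6 * order, class = "hrvkit_insufficient_data")
  filt <- bandpass_ecg(ecg, low = low, high = high, order = order)$samples
  d <- diff(filt)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[ecg$samples[cand] > threshold]
  refr <- max(1L, as.integer(round(refractory_s * ecg$fs)))
  if (length(cand) > 1) {
    # keep the largest raw-amplitude candidate within each refractory span
    ord <- cand[order(ecg$samples[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (i in ord)
      if (!length(kept) || min(abs(kept - i)) >= refr) kept <- c(kept, i)
    cand <- sort(kept)
  }
  peak_annotation(cand, fs = ecg$fs, n_samples = n,
                  threshold_used = threshold,
                  passband_used = c(low, high))
}

#' Add or remove detected peaks
#'
#' Programmatic equivalent of manual peak edition: fixed-threshold
#' detection can miss or over-call beats, and the user's judgement
#' overrides the algorithm — the refractory rule is *not* re-applied to
#' manual additions.
#'
#' @param ann A `peak_annotation`.
#' @param add Sample indices to add (must lie within the source record).
#' @param remove Sample indices to drop; removing an absent index warns
#'   and is otherwise a no-op.
#' @return The edited `peak_annotation`.
#' @export
edit_peaks <- function(ann, add = integer(0), remove = integer(0)) {
  stopifnot(inherits(ann, "peak_annotation"))
  add <- as.integer(add); remove <- as.integer(remove)
  if (length(add) && (any(add < 1) || any(add > ann$n_samples)))
    stop_hrv("added peak index out of bounds [1, %d]", ann$n_samples,
             class = "hrvkit_validation")
  missing <- setdiff(remove, ann$peak_indices)
  if (length(missing))
    warning(sprintf("index %s not present; nothing removed for it",
                    paste(missing, collapse = ", ")))
  peaks <- sort(unique(c(setdiff(ann$peak_indices, remove), add)))
  peak_annotation(peaks, fs = ann$fs, n_samples = ann$n_samples,
                  threshold_used = ann$threshold_used,
                  passband_used = ann$passband_used)
}

#' Convert R-peak annotations to an RR-interval series
#'
#' @param ann A `peak_annotation` with at least 2 peaks.
#' @return An [rri_series]: `values[j] = (peak[j+1] - peak[j]) / fs * 1000`
#'   ms, length `n_peaks - 1`.
#' @export
peaks_to_rri <- function(ann) {
  stopifnot(inherits(ann, "peak_annotation"))
  if (length(ann$peak_indices) < 2)
    stop_hrv("need at least 2 peaks to form RR intervals (got %d)",
             length(ann$peak_indices), class = "hrvkit_insufficient_data")
  rri_series(diff(ann$peak_indices) / ann$fs * 1000,
             label = "derived from R-peaks")
}
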