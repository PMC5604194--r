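#' RR-interval series (tachogram)
#'
#' Container for an ordered sequence of RR intervals in milliseconds. The
#' cumulative time axis (`onset_times`, seconds) marks the end of each
#' interval: the first interval ends at `values[1] / 1000` s, so the record
#' is taken to start at time 0.
#'
#' @param values Numeric vector of RR intervals in ms. Must be finite and
#'   strictly positive. A length-0 series is permitted (it can arise from
#'   aggressive artifact filtering); analysis functions enforce their own
#'   minimum lengths.
#' @param label Free-text provenance label.
#'
#' @return An object of class `rri_series` with elements `values` (ms),
#'   `onset_times` (s) and `label`.
#' @examples
#' rri <- rri_series(c(800, 810, 790))
#' rri$onset_times  # 0.80 1.61 2.40
#' @export
rri_series <- function(values, label = "") {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop_hrv("RR intervals must be finite numbers", class = "hrvkit_validation")
  if (any(values <= 0))
    stop_hrv("RR intervals must be strictly positive (got %g ms)",
             min(values), class = "hrvkit_validation")
  structure(list(values = values,
                 onset_times = cumsum(values) / 1000,
                 label = as.character(label)[1]),
            class = "rri_series")
}

#' @export
print.rri_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<rri_series> %d intervals, %.1f s", n,
              if (n) x$onset_times[n] else 0))
  if (nzchar(x$label)) cat(" [", x$label, "]", sep = "")
  cat("\n")
  if (n) cat("  mean RRi:", format(mean(x$values), digits = 6), "ms\n")
  invisible(x)
}

#' @export
length.rri_series <- function(x) length(x$values)

#' Evenly sampled ECG record
#'
#' @param samples Numeric vector of voltage samples (arbitrary units).
#' @param fs Sampling frequency in Hz (> 0).
#' @param start_time Time of the first sample, seconds.
#'
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, start_time = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop_hrv("sampling frequency must be a single positive number",
             class = "hrvkit_validation")
  if (length(samples) < 2)
    stop_hrv("an ECG record needs at least 2 samples",
             class = "hrvkit_validation")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop_hrv("ECG samples must be finite", class = "hrvkit_validation")
  structure(list(samples = samples, fs = fs, start_time = start_time),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Evenly resampled tachogram
#'
#' An RR-interval amplitude signal on a regular time grid, the form
#' consumed by the spectral estimators.
#'
#' @param values RRi amplitude in ms on the grid.
#' @param fs Grid (resampling) frequency, Hz.
#' @param t0 Time of the first grid point, seconds.
#'
#' @return An object of class `evenly_sampled_series`.
#' @export
evenly_sampled_series <- function(values, fs, t0 = 0) {
  values <- as.numeric(values)
  if (!is.finite(fs) || fs <= 0)
    stop_hrv("grid frequency must be positive", class = "hrvkit_validation")
  structure(list(values = values, fs = fs, t0 = t0),
            class = "evenly_sampled_series")
}

#' Time axis of an evenly sampled series
#' @param series An `evenly_sampled_series`.
#' @return Numeric vector of grid times in seconds.
#' @export
series_times <- function(series) {
  series$t0 + (seq_along(series$values) - 1) / series$fs
}

#' @export
print.evenly_sampled_series <- function(x, ...) {
  cat(sprintf("<evenly_sampled_series> %d points @ %g Hz from t0=%.2f s\n",
              length(x$values), x$fs, x$t0))
  invisible(x)
}
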