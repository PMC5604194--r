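# Non-stationary HRV analysis: windowed time-domain indices and
# short-time time-frequency band-power maps.

#' Time-varying (windowed) time-domain indices
#'
#' Computes every stationary time-domain index ([time_domain_indices]) in
#' successive short windows over the cumulative beat-time axis. Windows of
#' `segment_len_s` seconds start at `k * (segment_len_s - overlap_s)` from
#' time 0; an interval belongs to the window containing the time at which
#' it ends. Windows are half-open on the right, except the final window,
#' which is closed so a beat ending exactly at the record end belongs to
#' it. A trailing window that would extend past the record is dropped, not
#' padded. Windows holding fewer than 2 intervals yield `NA` indices.
#'
#' @param rri An [rri_series] spanning at least one window.
#' @param segment_len_s Window length, seconds (default 30).
#' @param overlap_s Overlap between consecutive windows, seconds
#'   (default 0; must be < `segment_len_s`).
#' @return A data.frame of class `time_varying_result`: one row per
#'   window with `segment_start_s`, `segment_end_s`, `n_beats` and the
#'   [time_domain_indices] columns.
#' @export
time_varying_indices <- function(rri, segment_len_s = 30, overlap_s = 0) {
  stopifnot(inherits(rri, "rri_series"))
  if (!is.finite(segment_len_s) || segment_len_s <= 0 ||
      !is.finite(overlap_s) || overlap_s < 0 || overlap_s >= segment_len_s)
    stop_hrv("need 0 <= overlap_s < segment_len_s",
             class = "hrvkit_validation")
  n <- length(rri$values)
  duration <- if (n) rri$onset_times[n] else 0
  if (duration < segment_len_s)
    stop_hrv("record spans %.1f s; shorter than one %g s segment",
             duration, segment_len_s, class = "hrvkit_insufficient_data")
  stride <- segment_len_s - overlap_s
  n_seg <- floor((duration - segment_len_s) / stride + 1e-9) + 1
  starts <- (seq_len(n_seg) - 1) * stride
  rows <- lapply(starts, function(s) {
    e <- s + segment_len_s
    last <- abs(e - duration) < 1e-9 || e > duration
    sel <- rri$onset_times >= s - 1e-9 &
      (rri$onset_times < e - 1e-9 | (last & rri$onset_times <= e + 1e-9))
    idx <- time_domain_indices(rri_series_unchecked(rri$values[sel]))
    cbind(data.frame(segment_start_s = s, segment_end_s = e,
                     n_beats = sum(sel)), idx)
  })
  out <- do.call(rbind, rows)
  attr(out, "segment_len_s") <- segment_len_s
  attr(out, "overlap_s") <- overlap_s
  class(out) <- c("time_varying_result", "data.frame")
  out
}

# Internal constructor bypassing the positivity check for empty windows.
rri_series_unchecked <- function(values) {
  structure(list(values = values, onset_times = cumsum(values) / 1000,
                 label = ""), class = "rri_series")
}

#' Short-time time-frequency band-power map
#'
#' Works like the Welch estimator — resample, detrend, split the evenly
#' sampled signal into windowed segments — but keeps each sub-segment's
#' PSD instead of averaging them, giving a time x frequency map; band
#' powers are then integrated per segment. Averaging the map's rows
#' recovers the Welch estimate of identical configuration.
#'
#' @param rri An [rri_series].
#' @param method `"welch_segment"` (windowed periodogram per segment) or
#'   `"ar"` (Burg model of `order` per segment).
#' @param fs Resampling frequency, Hz (default 4).
#' @param segment_len Segment length in samples of the resampled series
#'   (default 256).
#' @param overlap Overlap in samples (default 128); the shift is
#'   `segment_len - overlap`.
#' @param window Window for the periodogram method (default `"hann"`).
#' @param order Burg model order for `method = "ar"` (default 16).
#' @param padded_len Zero-padded transform length (default `segment_len`).
#' @param band_edges Band edges passed to [band_powers].
#' @param detrend_degree Global detrending degree applied once to the
#'   resampled signal (default 1); no per-segment detrending beyond mean
#'   removal is applied.
#' @return A `time_frequency_map`: `times` (segment centres, s), `freqs`
#'   (Hz), `power` (segments x frequency matrix, ms^2/Hz), `bands` (per-
#'   segment band-power data.frame) and `config`.
#' @export
time_frequency_map <- function(rri, method = c("welch_segment", "ar"),
                               fs = 4, segment_len = 256, overlap = 128,
                               window = "hann", order = 16,
                               padded_len = segment_len,
                               band_edges = c(0, 0.04, 0.15, 0.4),
                               detrend_degree = 1) {
  method <- match.arg(method)
  if (overlap < 0 || overlap >= segment_len)
    stop_hrv("need 0 <= overlap < segment_len", class = "hrvkit_validation")
  shift <- segment_len - overlap
  series <- interpolate_resample(rri, fs = fs)
  if (!is.null(detrend_degree))
    series <- detrend_polynomial(series, degree = detrend_degree)
  x <- series$values
  if (length(x) < segment_len)
    stop_hrv("resampled series has %d samples; need at least %d",
             length(x), segment_len, class = "hrvkit_insufficient_data")
  if (method == "welch_segment") {
    cfg <- welch_config(segment_len = segment_len, shift = shift,
                        window = window, padded_len = padded_len)
    wm <- welch_psd_matrix(x, fs, cfg)
    freqs <- wm$freqs
    mat <- wm$mat
    starts <- wm$starts
  } else {
    cfg <- ar_config(order = order, padded_len = padded_len)
    starts <- welch_segment_starts(length(x), segment_len, shift)
    nf <- floor(padded_len / 2) + 1
    mat <- t(vapply(starts, function(s) {
      seg <- evenly_sampled_series(x[s:(s + segment_len - 1L)], fs = fs)
      burg_psd(seg, cfg)$power
    }, numeric(nf)))
    freqs <- (seq_len(nf) - 1) * fs / padded_len
  }
  times <- series$t0 + (starts - 1 + (segment_len - 1) / 2) / fs
  bands <- do.call(rbind, lapply(seq_len(nrow(mat)), function(i) {
    bp <- band_powers(psd_estimate(freqs, mat[i, ], method = method),
                      edges = band_edges)
    data.frame(time_s = times[i], tp = bp$tp, vlf = bp$vlf, lf = bp$lf,
               hf = bp$hf, lf_hf = bp$lf_hf, lf_nu = bp$lf_nu,
               hf_nu = bp$hf_nu)
  }))
  structure(list(times = times, freqs = freqs, power = mat, bands = bands,
                 config = list(method = method, fs = fs,
                               segment_len = segment_len,
                               overlap = overlap, window = window,
                               order = order, padded_len = padded_len,
                               band_edges = band_edges,
                               detrend_degree = detrend_degree)),
            class = "time_frequency_map")
}

#' @export
print.time_frequency_map <- function(x, ...) {
  cat(sprintf("<time_frequency_map> %d segments x %d bins (%s), %.1f-%.1f s\n",
              nrow(x$power), ncol(x$power), x$config$method,
              min(x$times), max(x$times)))
  invisible(x)
}
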