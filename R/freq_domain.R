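# Spectral HRV analysis: Welch averaged periodogram, Burg autoregressive
# PSD, and trapezoidal band-power integration.

#' Welch estimator configuration
#'
#' @param segment_len Segment length D in samples (default 256).
#' @param shift Shift S between adjacent segments in samples (default 128,
#'   i.e. 50% overlap). The segment count is `floor((N - D) / S) + 1`.
#' @param window Taper applied to each segment: one of `"hann"`,
#'   `"hamming"`, `"kaiser"`, `"blackman"`, `"triangular"`,
#'   `"rectangular"`.
#' @param kaiser_beta Kaiser shape parameter (default 8.6, ~ Blackman-like
#'   sidelobes).
#' @param padded_len Zero-padded transform length (>= `segment_len`;
#'   default equal, i.e. no padding). Padding refines the frequency grid
#'   without adding information.
#' @return A `welch_config` list.
#' @export
welch_config <- function(segment_len = 256, shift = 128, window = "hann",
                         kaiser_beta = 8.6, padded_len = segment_len) {
  segment_len <- as.integer(segment_len)
  shift <- as.integer(shift)
  padded_len <- as.integer(padded_len)
  if (shift < 1 || shift > segment_len || segment_len > padded_len)
    stop_hrv("need 1 <= shift <= segment_len <= padded_len",
             class = "hrvkit_validation")
  window <- match.arg(window, c("hann", "hamming", "kaiser", "blackman",
                                "triangular", "rectangular"))
  structure(list(segment_len = segment_len, shift = shift, window = window,
                 kaiser_beta = kaiser_beta, padded_len = padded_len),
            class = "welch_config")
}

#' Autoregressive (Burg) estimator configuration
#'
#' @param order AR model order (default 16).
#' @param padded_len Length controlling the frequency-grid resolution on
#'   which the model's frequency response is evaluated (default 1024).
#' @return An `ar_config` list.
#' @export
ar_config <- function(order = 16, padded_len = 1024) {
  order <- as.integer(order)
  padded_len <- as.integer(padded_len)
  if (order < 0) stop_hrv("AR order must be >= 0",
                          class = "hrvkit_validation")
  if (padded_len < 2) stop_hrv("padded_len must be >= 2",
                               class = "hrvkit_validation")
  structure(list(order = order, padded_len = padded_len),
            class = "ar_config")
}

window_coefs <- function(name, n, kaiser_beta = 8.6) {
  if (n == 1) return(1)
  switch(name,
         rectangular = rep(1, n),
         hann = signal::hanning(n),
         hamming = signal::hamming(n),
         blackman = signal::blackman(n),
         triangular = signal::triang(n),
         kaiser = signal::kaiser(n, kaiser_beta),
         stop_hrv("unknown window '%s'", name,
                  class = "hrvkit_validation"))
}

psd_estimate <- function(freqs, power, method, n_segments_averaged = NA,
                         config = NULL) {
  structure(list(freqs = freqs, power = pmax(power, 0), method = method,
                 n_segments_averaged = n_segments_averaged,
                 config = config),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> method=%s, %d bins up to %g Hz",
              x$method, length(x$freqs), max(x$freqs)))
  if (!is.na(x$n_segments_averaged))
    cat(sprintf(", %d segments averaged", x$n_segments_averaged))
  cat("\n")
  invisible(x)
}

# One-sided windowed periodogram of a single segment. The segment mean is
# removed before tapering (prevents DC leakage into VLF); density is
# normalised by fs * sum(w^2) so that the trapezoidal integral of a
# rectangular-window estimate recovers the segment variance. Interior bins
# are doubled; DC and (for even padded_len) Nyquist are not.
segment_periodogram <- function(seg, fs, w, padded_len) {
  seg <- (seg - mean(seg)) * w
  if (padded_len > length(seg)) seg <- c(seg, numeric(padded_len - length(seg)))
  nf <- floor(padded_len / 2) + 1
  X <- stats::fft(seg)[seq_len(nf)]
  p <- Mod(X)^2 / (fs * sum(w^2))
  scale <- rep(2, nf)
  scale[1] <- 1
  if (padded_len %% 2 == 0) scale[nf] <- 1
  p * scale
}

welch_segment_starts <- function(n, d, s) seq(1L, n - d + 1L, by = s)

# Matrix of per-segment one-sided PSDs (segments in rows) plus the shared
# frequency grid; the common core of welch_psd and time_frequency_map.
welch_psd_matrix <- function(values, fs, cfg) {
  n <- length(values)
  if (n < cfg$segment_len)
    stop_hrv("series has %d samples; Welch segments of %d need at least %d",
             n, cfg$segment_len, cfg$segment_len,
             class = "hrvkit_insufficient_data")
  w <- window_coefs(cfg$window, cfg$segment_len, cfg$kaiser_beta)
  starts <- welch_segment_starts(n, cfg$segment_len, cfg$shift)
  nf <- floor(cfg$padded_len / 2) + 1
  freqs <- (seq_len(nf) - 1) * fs / cfg$padded_len
  mat <- t(vapply(starts, function(s)
    segment_periodogram(values[s:(s + cfg$segment_len - 1L)], fs, w,
                        cfg$padded_len),
    numeric(nf)))
  list(freqs = freqs, mat = mat, starts = starts)
}

#' Welch averaged-periodogram PSD of an evenly sampled tachogram
#'
#' Splits the series into `P = floor((N - D) / S) + 1` segments of length
#' `D` shifted by `S`, removes each segment's mean, applies the window,
#' zero-pads, and averages the one-sided periodograms. Density units are
#' ms^2/Hz when the input is in ms.
#'
#' @param series An [evenly_sampled_series].
#' @param cfg A [welch_config].
#' @return A `psd_estimate` (fields `freqs`, `power`, `method`,
#'   `n_segments_averaged`, `config`).
#' @export
welch_psd <- function(series, cfg = welch_config()) {
  stopifnot(inherits(series, "evenly_sampled_series"),
            inherits(cfg, "welch_config"))
  wm <- welch_psd_matrix(series$values, series$fs, cfg)
  psd_estimate(wm$freqs, colMeans(wm$mat), method = "welch",
               n_segments_averaged = nrow(wm$mat), config = cfg)
}

# Burg recursion in the monic convention A(z) = 1 + a_1 z^-1 + ... +
# a_p z^-p: each reflection coefficient minimises the summed forward and
# backward prediction-error power. Returns coefficients a and the final
# per-sample prediction-error power.
burg_coefficients <- function(x, order) {
  n <- length(x)
  ef <- eb <- x
  a <- numeric(0)
  e <- sum(x^2) / n
  for (m in seq_len(order)) {
    efp <- ef[-1]
    ebp <- eb[-length(eb)]
    den <- sum(efp^2) + sum(ebp^2)
    k <- if (den > 0) -2 * sum(efp * ebp) / den else 0
    a <- c(a, 0) + k * c(rev(a), 1)
    e <- e * (1 - k^2)
    ef <- efp + k * ebp
    eb <- ebp + k * efp
  }
  list(a = a, sigma2 = e)
}

#' Burg autoregressive PSD of an evenly sampled tachogram
#'
#' Fits an AR(p) model by the Burg method — reflection coefficients chosen
#' to minimise the summed forward and backward prediction error at each
#' order — and evaluates the one-sided density from the model's frequency
#' response: `2 * sigma^2 / (fs * |1 + sum a_k exp(-i 2 pi f k / fs)|^2)`
#' on the interior of the grid (DC and Nyquist are not doubled). The
#' series mean is removed before fitting.
#'
#' @param series An [evenly_sampled_series] longer than `order`.
#' @param cfg An [ar_config].
#' @return A `psd_estimate` whose `config` also records the fitted
#'   coefficients (`a`, monic convention) and prediction-error power
#'   (`sigma2`).
#' @export
burg_psd <- function(series, cfg = ar_config()) {
  stopifnot(inherits(series, "evenly_sampled_series"),
            inherits(cfg, "ar_config"))
  x <- series$values
  fs <- series$fs
  if (cfg$order >= length(x))
    stop_hrv("AR order %d must be below the series length %d",
             cfg$order, length(x), class = "hrvkit_validation")
  x <- x - mean(x)
  nf <- floor(cfg$padded_len / 2) + 1
  freqs <- (seq_len(nf) - 1) * fs / cfg$padded_len
  if (sum(x^2) == 0) {
    warning("input has zero variance; returning a flat-zero PSD")
    return(psd_estimate(freqs, numeric(nf), method = "ar", config = cfg))
  }
  fit <- burg_coefficients(x, cfg$order)
  A <- rep(1 + 0i, nf)
  for (k in seq_along(fit$a))
    A <- A + fit$a[k] * exp(-2i * pi * freqs * k / fs)
  p <- fit$sigma2 / (fs * Mod(A)^2)
  scale <- rep(2, nf)
  scale[1] <- 1
  if (cfg$padded_len %% 2 == 0) scale[nf] <- 1
  cfg$a <- fit$a
  cfg$sigma2 <- fit$sigma2
  psd_estimate(freqs, p * scale, method = "ar", config = cfg)
}

# Trapezoidal integral of the density over [lo, hi], with the density
# linearly interpolated at the exact band edges so contiguous bands tile
# without gap or overlap.
band_integral <- function(freqs, power, lo, hi) {
  if (hi <= lo) return(0)
  inner <- freqs > lo & freqs < hi
  f <- c(lo, freqs[inner], hi)
  p <- stats::approx(freqs, power, xout = f, rule = 2)$y
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

#' Normalized units and LF/HF ratio from band powers
#'
#' `LFnu = 100 * LF / (TP - VLF)` and `HFnu = 100 * HF / (TP - VLF)`. With
#' contiguous bands `TP - VLF = LF + HF`, so `tp` may be omitted and is
#' then reconstructed as `vlf + lf + hf`.
#'
#' @param lf,hf Absolute band powers, ms^2.
#' @param tp Total power, ms^2 (default `vlf + lf + hf`).
#' @param vlf Very-low-frequency power, ms^2 (default 0).
#' @return Named vector `c(lf_nu =, hf_nu =, lf_hf =)`; `lf_hf` is `NA`
#'   when `hf` is 0, and the normalized units are `NA` when `tp <= vlf`.
#' @export
band_ratios <- function(lf, hf, tp = NULL, vlf = 0) {
  if (is.null(tp)) tp <- vlf + lf + hf
  denom <- tp - vlf
  c(lf_nu = if (denom > 0) 100 * lf / denom else NA_real_,
    hf_nu = if (denom > 0) 100 * hf / denom else NA_real_,
    lf_hf = if (hf > 0) lf / hf else NA_real_)
}

#' Spectral band powers from a PSD estimate
#'
#' Integrates the one-sided density over the VLF, LF and HF bands (and
#' their union, TP) by the trapezoidal rule with edge interpolation, and
#' derives LF/HF and normalized units ([band_ratios]).
#'
#' @param psd A `psd_estimate`.
#' @param edges Ascending band edges in Hz:
#'   `c(vlf_lo, vlf_hi, lf_hi, hf_hi)`, default `c(0, 0.04, 0.15, 0.4)`.
#' @return A `band_powers` list: `tp`, `vlf`, `lf`, `hf` (ms^2), `lf_hf`,
#'   `lf_nu`, `hf_nu` (%), `band_edges`.
#' @export
band_powers <- function(psd, edges = c(0, 0.04, 0.15, 0.4)) {
  stopifnot(inherits(psd, "psd_estimate"))
  if (length(edges) != 4 || is.unsorted(edges, strictly = TRUE))
    stop_hrv("edges must be 4 strictly ascending values (Hz)",
             class = "hrvkit_validation")
  if (edges[1] < 0 || edges[4] > max(psd$freqs) + 1e-12)
    stop_hrv("band edges must lie within [0, %g] Hz", max(psd$freqs),
             class = "hrvkit_validation")
  vlf <- band_integral(psd$freqs, psd$power, edges[1], edges[2])
  lf <- band_integral(psd$freqs, psd$power, edges[2], edges[3])
  hf <- band_integral(psd$freqs, psd$power, edges[3], edges[4])
  tp <- band_integral(psd$freqs, psd$power, edges[1], edges[4])
  r <- band_ratios(lf, hf, tp = tp, vlf = vlf)
  structure(list(tp = tp, vlf = vlf, lf = lf, hf = hf,
                 lf_hf = r[["lf_hf"]], lf_nu = r[["lf_nu"]],
                 hf_nu = r[["hf_nu"]], band_edges = edges),
            class = "band_powers")
}

#' @export
print.band_powers <- function(x, ...) {
  cat(sprintf(paste0("<band_powers> TP=%.2f VLF=%.2f LF=%.2f HF=%.2f ms^2",
                     " | LF/HF=%.2f LFnu=%.2f HFnu=%.2f\n"),
              x$tp, x$vlf, x$lf, x$hf, x$lf_hf, x$lf_nu, x$hf_nu))
  invisible(x)
}

#' Full frequency-domain analysis of a tachogram
#'
#' End-to-end pipeline: cubic-spline resampling
#' ([interpolate_resample]) -> polynomial detrending
#' ([detrend_polynomial]) -> PSD estimation ([welch_psd] or [burg_psd]) ->
#' band integration ([band_powers]).
#'
#' @param rri An [rri_series].
#' @param method `"welch"` or `"ar"`.
#' @param fs Resampling frequency, Hz (default 4).
#' @param detrend_degree Detrending polynomial degree (default 1, linear);
#'   `NULL` skips detrending.
#' @param cfg A [welch_config] or [ar_config] matching `method`; defaults
#'   are used when `NULL`.
#' @param band_edges Band edges passed to [band_powers].
#' @return A list with `psd` (the `psd_estimate`) and `bands` (the
#'   `band_powers`).
#' @export
frequency_analysis <- function(rri, method = c("welch", "ar"), fs = 4,
                               detrend_degree = 1, cfg = NULL,
                               band_edges = c(0, 0.04, 0.15, 0.4)) {
  method <- match.arg(method)
  series <- interpolate_resample(rri, fs = fs)
  if (!is.null(detrend_degree))
    series <- detrend_polynomial(series, degree = detrend_degree)
  psd <- if (method == "welch") {
    welch_psd(series, cfg %||% welch_config())
  } else {
    burg_psd(series, cfg %||% ar_config())
  }
  list(psd = psd, bands = band_powers(psd, edges = band_edges))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
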