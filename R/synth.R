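# Seeded synthetic signal generators with analytic ground truth. These
# emulate the structure the spectral bands assume — LF/HF sinusoidal
# oscillations riding on a mean RR level — plus polynomial trend, white
# noise and planted ectopic beats, so every analysis stage can be tested
# against known truth.

polyval_asc <- function(coefs, t) {
  # coefficients in ascending order: coefs[1] + coefs[2] * t + ...
  if (!length(coefs)) return(rep(0, length(t)))
  out <- rep(0, length(t))
  for (k in seq_along(coefs)) out <- out + coefs[k] * t^(k - 1)
  out
}

#' Synthetic tachogram with known tone powers
#'
#' Generates beat times iteratively: the next beat follows the previous
#' one by the current RR value, where
#' `RRi(t) = mean + sum(A * sin(2 pi f t + phase)) + trend(t) + noise`.
#' This amplitude-modulation scheme is adequate ground truth at the
#' modulation depths used in testing (tones well below the mean level);
#' each pure tone contributes an analytic power of `A^2 / 2` ms^2 to its
#' band. Ectopic beats are planted afterwards by scaling single
#' intervals.
#'
#' @param duration_s Record duration, seconds.
#' @param mean_rri_ms Mean RR interval, ms (default 900).
#' @param tones Data.frame with columns `freq_hz`, `amp_ms` and
#'   optionally `phase` (rad), one row per sinusoidal component. Tone
#'   frequencies must stay below 0.5 Hz.
#' @param noise_sd_ms Per-beat white-noise standard deviation, ms.
#' @param trend Polynomial trend coefficients in ascending powers of time
#'   (ms, ms/s, ms/s^2, ...).
#' @param ectopics Data.frame with columns `beat` (index) and `scale`;
#'   each listed interval is multiplied by its scale factor.
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @return A list with `rri` (the [rri_series]) and `truth` (analytic
#'   tone powers `A^2 / 2` named by frequency, planted `ectopic_indices`,
#'   and the generating parameters).
#' @export
make_tachogram <- function(duration_s, mean_rri_ms = 900, tones = NULL,
                           noise_sd_ms = 0, trend = numeric(0),
                           ectopics = NULL, seed = NULL) {
  if (!is.finite(duration_s) || duration_s <= 0)
    stop_hrv("duration must be positive", class = "hrvkit_validation")
  if (!is.null(tones)) {
    stopifnot(all(c("freq_hz", "amp_ms") %in% names(tones)))
    if (is.null(tones$phase)) tones$phase <- 0
    if (any(tones$freq_hz <= 0) || any(tones$freq_hz >= 0.5))
      stop_hrv("tone frequencies must lie in (0, 0.5) Hz",
               class = "hrvkit_validation")
  }
  values <- with_seed(seed, {
    t <- 0
    out <- numeric(0)
    repeat {
      rr <- mean_rri_ms + polyval_asc(trend, t)
      if (!is.null(tones))
        rr <- rr + sum(tones$amp_ms *
                         sin(2 * pi * tones$freq_hz * t + tones$phase))
      if (noise_sd_ms > 0) rr <- rr + stats::rnorm(1, 0, noise_sd_ms)
      if (rr <= 0)
        stop_hrv("generator produced a non-positive RR interval at t=%.1f s",
                 t, class = "hrvkit_validation")
      if (t + rr / 1000 > duration_s) break
      out <- c(out, rr)
      t <- t + rr / 1000
    }
    out
  })
  ectopic_indices <- integer(0)
  if (!is.null(ectopics) && nrow(ectopics)) {
    stopifnot(all(c("beat", "scale") %in% names(ectopics)))
    if (any(ectopics$beat < 1) || any(ectopics$beat > length(values)))
      stop_hrv("ectopic beat index out of range",
               class = "hrvkit_validation")
    values[ectopics$beat] <- values[ectopics$beat] * ectopics$scale
    if (any(values <= 0))
      stop_hrv("ectopic scaling produced a non-positive interval",
               class = "hrvkit_validation")
    ectopic_indices <- sort(as.integer(ectopics$beat))
  }
  truth <- list(
    tone_powers = if (is.null(tones)) numeric(0) else
      stats::setNames(tones$amp_ms^2 / 2, tones$freq_hz),
    ectopic_indices = ectopic_indices,
    mean_rri_ms = mean_rri_ms, noise_sd_ms = noise_sd_ms,
    trend = trend, seed = seed)
  list(rri = rri_series(values, label = "synthetic tachogram"),
       truth = truth)
}

#' Synthetic ECG with planted R-peaks
#'
#' One Gaussian bump per beat on a zero baseline, plus optional white
#' noise. Each bump is centred on the sample nearest its beat time, so in
#' the noise-free signal the maximum equals `r_amplitude` exactly at the
#' planted index.
#'
#' @param beat_times_s Beat times, seconds; consecutive beats must be
#'   more than `3 * qrs_sigma_s` apart (closer bumps would merge).
#' @param fs Sampling frequency, Hz.
#' @param r_amplitude R-wave amplitude (arbitrary units, default 1).
#' @param qrs_sigma_s Gaussian width of the QRS bump, seconds
#'   (default 0.01, i.e. 10 ms).
#' @param noise_sd Additive white-noise standard deviation (default 0).
#' @param seed Integer seed for the noise.
#' @param duration_s Record length, seconds (default: last beat + 0.5 s).
#' @return A list with `ecg` (the [ecg_record]) and `planted_indices`
#'   (1-based sample indices of the true peaks).
#' @export
make_ecg <- function(beat_times_s, fs, r_amplitude = 1, qrs_sigma_s = 0.01,
                     noise_sd = 0, seed = NULL, duration_s = NULL) {
  beat_times_s <- sort(as.numeric(beat_times_s))
  if (!length(beat_times_s) || any(beat_times_s < 0))
    stop_hrv("beat times must be non-negative", class = "hrvkit_validation")
  if (!is.finite(qrs_sigma_s) || qrs_sigma_s <= 0)
    stop_hrv("qrs_sigma_s must be positive", class = "hrvkit_validation")
  if (length(beat_times_s) > 1 &&
      min(diff(beat_times_s)) <= 3 * qrs_sigma_s)
    stop_hrv("beats closer than 3 sigma (%g s) would overlap",
             3 * qrs_sigma_s, class = "hrvkit_validation")
  if (is.null(duration_s)) duration_s <- max(beat_times_s) + 0.5
  if (max(beat_times_s) > duration_s)
    stop_hrv("beat times must lie within the record duration",
             class = "hrvkit_validation")
  n <- ceiling(duration_s * fs)
  planted <- as.integer(round(beat_times_s * fs)) + 1L
  x <- numeric(n)
  half <- ceiling(6 * qrs_sigma_s * fs)
  for (p in planted) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    tt <- (lo:hi - p) / fs
    x[lo:hi] <- x[lo:hi] + r_amplitude * exp(-tt^2 / (2 * qrs_sigma_s^2))
  }
  if (noise_sd > 0)
    x <- x + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  list(ecg = ecg_record(x, fs = fs), planted_indices = planted)
}

#' Simulated stationary autoregressive process
#'
#' Simulates `x_t = sum(coeffs[k] * x_{t-k}) + e_t` with Gaussian
#' innovations, discarding a 500-sample burn-in to remove transient bias.
#' Stationarity is checked via the spectral radius of the companion
#' matrix.
#'
#' @param coeffs AR coefficients in the process (regression) convention;
#'   `numeric(0)` gives white noise.
#' @param noise_sd Innovation standard deviation (default 1).
#' @param n Output length after burn-in.
#' @param seed Integer seed.
#' @param fs Nominal sampling frequency attached to the output grid
#'   (default 1).
#' @return An [evenly_sampled_series].
#' @export
make_ar_process <- function(coeffs, noise_sd = 1, n, seed = NULL, fs = 1) {
  coeffs <- as.numeric(coeffs)
  p <- length(coeffs)
  if (p) {
    comp <- matrix(0, p, p)
    comp[1, ] <- coeffs
    if (p > 1) comp[cbind(2:p, 1:(p - 1))] <- 1
    if (max(Mod(eigen(comp, only.values = TRUE)$values)) >= 1)
      stop_hrv("AR coefficients are not stationary",
               class = "hrvkit_validation")
  }
  burn <- 500
  x <- with_seed(seed, {
    e <- stats::rnorm(n + burn, 0, noise_sd)
    if (!p) {
      e
    } else {
      out <- numeric(n + burn)
      for (t in seq_len(n + burn)) {
        past <- 0
        for (k in seq_len(min(p, t - 1)))
          past <- past + coeffs[k] * out[t - k]
        out[t] <- past + e[t]
      }
      out
    }
  })
  evenly_sampled_series(x[(burn + 1):(burn + n)], fs = fs)
}

#' Exercise-like non-stationary tachogram
#'
#' Emulates an incremental exercise test with recovery: a resting phase,
#' a work ramp over which the mean RR interval falls linearly and the
#' LF/HF oscillation amplitudes decay exponentially (vagal withdrawal),
#' and a recovery phase with exponential return of both. Useful for
#' exercising the time-varying and time-frequency engines on a record
#' whose variability trajectory is known by construction.
#'
#' @param pre_s,ramp_s,recovery_s Phase durations, seconds (defaults
#'   180 / 480 / 300).
#' @param rest_mean_ms Resting mean RR, ms (default 900).
#' @param peak_mean_ms Mean RR at exhaustion, ms (default 350).
#' @param recovery_mean_ms Asymptotic recovery mean RR, ms (default 600).
#' @param lf_tone,hf_tone `c(freq_hz, amp_ms)` of the two oscillations
#'   (defaults `c(0.1, 30)` and `c(0.25, 20)`).
#' @param noise_sd_ms Per-beat noise at rest, ms (default 1); scaled with
#'   the oscillation envelope.
#' @param seed Integer seed.
#' @return A list with `rri` and `truth` (phase boundaries `pre_end_s`,
#'   `ramp_end_s`, `duration_s`, and the envelope function `amp_scale`).
#' @export
make_exercise_tachogram <- function(pre_s = 180, ramp_s = 480,
                                    recovery_s = 300, rest_mean_ms = 900,
                                    peak_mean_ms = 350,
                                    recovery_mean_ms = 600,
                                    lf_tone = c(0.1, 30),
                                    hf_tone = c(0.25, 20),
                                    noise_sd_ms = 1, seed = NULL) {
  duration <- pre_s + ramp_s + recovery_s
  # Mean RR recovers on the fast (~40 s) phase of heart-rate recovery;
  # the oscillation envelope recovers on the much slower (~150 s) time
  # scale of vagal reactivation, so HRV keeps rising throughout recovery.
  mean_at <- function(t) {
    if (t < pre_s) return(rest_mean_ms)
    if (t < pre_s + ramp_s)
      return(rest_mean_ms +
               (peak_mean_ms - rest_mean_ms) * (t - pre_s) / ramp_s)
    recovery_mean_ms +
      (peak_mean_ms - recovery_mean_ms) * exp(-(t - pre_s - ramp_s) / 40)
  }
  amp_scale <- function(t) {
    if (t < pre_s) return(1)
    if (t < pre_s + ramp_s) return(exp(-4 * (t - pre_s) / ramp_s))
    end_scale <- exp(-4)
    end_scale + (0.4 - end_scale) * (1 - exp(-(t - pre_s - ramp_s) / 150))
  }
  values <- with_seed(seed, {
    t <- 0
    out <- numeric(0)
    repeat {
      a <- amp_scale(t)
      rr <- mean_at(t) +
        a * lf_tone[2] * sin(2 * pi * lf_tone[1] * t) +
        a * hf_tone[2] * sin(2 * pi * hf_tone[1] * t)
      if (noise_sd_ms > 0)
        rr <- rr + stats::rnorm(1, 0, noise_sd_ms * max(a, 0.1))
      if (t + rr / 1000 > duration) break
      out <- c(out, rr)
      t <- t + rr / 1000
    }
    out
  })
  list(rri = rri_series(values, label = "synthetic exercise tachogram"),
       truth = list(pre_end_s = pre_s, ramp_end_s = pre_s + ramp_s,
                    duration_s = duration, amp_scale = amp_scale))
}
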