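#' Moving-average filter for a tachogram
#'
#' Convolves the RR-interval series with a length-`order` boxcar of 1/N
#' weights, centred on each beat. Edge windows are truncated to the
#' available points so the series keeps its length.
#'
#' @param rri An [rri_series].
#' @param order Window length N (>= 1, <= series length). For even N the
#'   window extends `floor((N-1)/2)` beats left and `floor(N/2)` right.
#' @return A filtered [rri_series] of the same length.
#' @export
moving_average_filter <- function(rri, order) {
  stopifnot(inherits(rri, "rri_series"))
  n <- length(rri$values)
  if (!is.finite(order) || order < 1 || order != round(order))
    stop_hrv("filter order must be a positive integer",
             class = "hrvkit_validation")
  if (order > n)
    stop_hrv("filter order %d exceeds series length %d", order, n,
             class = "hrvkit_validation")
  left <- floor((order - 1) / 2); right <- floor(order / 2)
  out <- vapply(seq_len(n), function(j)
    mean(rri$values[max(1, j - left):min(n, j + right)]), numeric(1))
  rri_series(out, label = rri$label)
}

#' Moving-median filter for a tachogram
#'
#' Replaces each beat by the median of the odd-length window centred on
#' it; robust to single ectopic outliers. Edge windows are truncated.
#'
#' @param rri An [rri_series].
#' @param order Odd window length N (>= 1, <= series length).
#' @return A filtered [rri_series] of the same length.
#' @export
moving_median_filter <- function(rri, order) {
  stopifnot(inherits(rri, "rri_series"))
  n <- length(rri$values)
  if (!is.finite(order) || order < 1 || order != round(order))
    stop_hrv("filter order must be a positive integer",
             class = "hrvkit_validation")
  if (order %% 2 == 0)
    stop_hrv("moving-median order must be odd (got %d)", order,
             class = "hrvkit_validation")
  if (order > n)
    stop_hrv("filter order %d exceeds series length %d", order, n,
             class = "hrvkit_validation")
  h <- (order - 1) / 2
  out <- vapply(seq_len(n), function(j)
    stats::median(rri$values[max(1, j - h):min(n, j + h)]), numeric(1))
  rri_series(out, label = rri$label)
}

#' Quotient filter for ectopic-beat removal
#'
#' Flags every beat whose ratio with either neighbour is `>= 1.2` or
#' `<= 0.8` (a beat-to-beat variation of 20% or more; endpoints are judged
#' against their single neighbour). All flags are computed on the original
#' series, then the flagged beats are removed in a single pass — the rule
#' is not iterated.
#'
#' @param rri An [rri_series] with at least 2 intervals.
#' @return A list with `rri` (the filtered [rri_series]; possibly empty —
#'   e.g. a two-beat series violating the rule removes both) and `removed`
#'   (1-based indices into the input).
#' @export
quotient_filter <- function(rri) {
  stopifnot(inherits(rri, "rri_series"))
  v <- rri$values
  n <- length(v)
  if (n < 2)
    stop_hrv("quotient filter needs at least 2 intervals",
             class = "hrvkit_insufficient_data")
  bad_ratio <- function(r) r >= 1.2 | r <= 0.8
  with_prev <- c(FALSE, bad_ratio(v[-1] / v[-n]))
  with_next <- c(bad_ratio(v[-n] / v[-1]), FALSE)
  flagged <- with_prev | with_next
  out <- if (all(flagged)) rri_series(numeric(0), label = rri$label)
         else rri_series(v[!flagged], label = rri$label)
  list(rri = out, removed = which(flagged))
}

#' Polynomial detrending of an evenly sampled tachogram
#'
#' Fits a least-squares polynomial of the given degree in time and
#' subtracts it, suppressing slow non-stationary drift that would
#' otherwise leak into the VLF band. Degree 1 (linear) is the default;
#' quadratic, cubic or any custom degree up to `n - 1` is accepted.
#'
#' @param series An [evenly_sampled_series].
#' @param degree Polynomial degree, `1 <= degree <= length - 1`.
#' @return The detrended [evenly_sampled_series] (residuals; mean ~ 0).
#' @export
detrend_polynomial <- function(series, degree = 1) {
  stopifnot(inherits(series, "evenly_sampled_series"))
  n <- length(series$values)
  if (!is.finite(degree) || degree < 1 || degree > n - 1 ||
      degree != round(degree))
    stop_hrv("detrend degree must be an integer in [1, %d]", n - 1,
             class = "hrvkit_validation")
  t <- series_times(series)
  fit <- stats::lm(series$values ~ stats::poly(t, degree))
  evenly_sampled_series(stats::residuals(fit), fs = series$fs,
                        t0 = series$t0)
}

#' Cubic-spline interpolation and even resampling of a tachogram
#'
#' Interpolates RR-interval amplitude against the cumulative beat time
#' with a cubic spline and evaluates it on an even grid from the first to
#' the last beat onset at step `1 / fs`. An evenly sampled signal is what
#' Fourier and AR spectral estimators require; 4 Hz is the conventional
#' resampling rate for human tachograms.
#'
#' @param rri An [rri_series] with at least 4 beats.
#' @param fs Resampling frequency, Hz (default 4).
#' @return An [evenly_sampled_series].
#' @export
interpolate_resample <- function(rri, fs = 4) {
  stopifnot(inherits(rri, "rri_series"))
  if (!is.finite(fs) || fs <= 0)
    stop_hrv("resampling frequency must be positive",
             class = "hrvkit_validation")
  n <- length(rri$values)
  if (n < 4)
    stop_hrv("cubic-spline resampling needs at least 4 beats (got %d)",
             n, class = "hrvkit_insufficient_data")
  t0 <- rri$onset_times[1]
  tn <- rri$onset_times[n]
  grid <- t0 + (0:floor((tn - t0) * fs)) / fs
  sf <- stats::splinefun(rri$onset_times, rri$values, method = "fmm")
  evenly_sampled_series(sf(grid), fs = fs, t0 = t0)
}
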