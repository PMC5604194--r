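# Stationary time-domain HRV indices. All take an rri_series in ms.

check_rri_length <- function(rri, min, what) {
  stopifnot(inherits(rri, "rri_series"))
  if (length(rri$values) < min)
    stop_hrv("%s needs at least %d intervals (got %d)", what, min,
             length(rri$values), class = "hrvkit_insufficient_data")
}

#' SDNN: standard deviation of RR intervals
#'
#' Sample standard deviation (N - 1 denominator) of the interval series;
#' reflects both short- and long-term variability.
#'
#' @param rri An [rri_series] (>= 2 intervals).
#' @return SDNN in ms.
#' @export
sdnn <- function(rri) {
  check_rri_length(rri, 2, "SDNN")
  stats::sd(rri$values)
}

#' RMSSD: root mean square of successive differences
#'
#' `sqrt(sum(diff^2) / (N - 1))` over the N - 1 successive differences of
#' an N-interval series; the classical short-term (vagal) variability
#' index.
#'
#' @param rri An [rri_series] (>= 2 intervals).
#' @return RMSSD in ms.
#' @export
rmssd <- function(rri) {
  check_rri_length(rri, 2, "RMSSD")
  sqrt(mean(diff(rri$values)^2))
}

#' SDSD: standard deviation of successive differences
#'
#' @param rri An [rri_series] (>= 3 intervals).
#' @return SDSD in ms (sample standard deviation of the differences).
#' @export
sdsd <- function(rri) {
  check_rri_length(rri, 3, "SDSD")
  stats::sd(diff(rri$values))
}

#' Poincare plot descriptors SD1 and SD2
#'
#' Dispersion of the `RRi[n]` vs `RRi[n+1]` scatter perpendicular to
#' (SD1, short-term) and along (SD2, long-term) the identity line:
#' `SD1 = SDSD / sqrt(2)` and `SD2 = sqrt(2 SDNN^2 - SDSD^2 / 2)`. These
#' forms satisfy `SD1^2 + SD2^2 = 2 SDNN^2` exactly. A negative SD2
#' radicand (possible only through floating rounding) is clamped to 0.
#'
#' @param rri An [rri_series] (>= 3 intervals).
#' @return Named numeric vector `c(sd1 =, sd2 =)` in ms.
#' @export
poincare_sd <- function(rri) {
  check_rri_length(rri, 3, "Poincare SD1/SD2")
  s <- stats::sd(rri$values)
  d <- stats::sd(diff(rri$values))
  sd1 <- d / sqrt(2)
  sd2 <- sqrt(max(0, 2 * s^2 - d^2 / 2))
  c(sd1 = sd1, sd2 = sd2)
}

#' NN50 and pNN50
#'
#' NN50 counts successive differences strictly greater than 50 ms in
#' absolute value. pNN50 expresses the count as a percentage; the default
#' denominator is the total interval count N. The more common convention
#' divides by the N - 1 differences instead; it is available via
#' `denominator = "n-1"`.
#'
#' @param rri An [rri_series] (>= 2 intervals).
#' @param denominator `"n"` (default) or `"n-1"`.
#' @return Named numeric vector `c(nn50 =, pnn50 =)` (count, percent).
#' @export
nn50_pnn50 <- function(rri, denominator = c("n", "n-1")) {
  check_rri_length(rri, 2, "NN50/pNN50")
  denominator <- match.arg(denominator)
  n <- length(rri$values)
  nn50 <- sum(abs(diff(rri$values)) > 50)
  den <- if (denominator == "n") n else n - 1
  c(nn50 = nn50, pnn50 = 100 * nn50 / den)
}

#' Mean RR interval, mean heart rate and mean successive difference
#'
#' `mean_hr` averages the instantaneous beat-wise heart rate
#' `60000 / RRi[j]` (bpm). The alternative convention `60000 / mean(RRi)`
#' — the two differ whenever the series is not constant — is available via
#' `hr_method = "overall"`.
#'
#' @param rri An [rri_series] (>= 1 interval; >= 2 for the mean successive
#'   difference, which is `NA` otherwise).
#' @param hr_method `"instantaneous"` (default) or `"overall"`.
#' @return Named vector `c(mean_rri =, mean_hr =, mean_succ_diff =)`
#'   (ms, bpm, ms; the successive difference is signed).
#' @export
mean_indices <- function(rri, hr_method = c("instantaneous", "overall")) {
  check_rri_length(rri, 1, "mean indices")
  hr_method <- match.arg(hr_method)
  v <- rri$values
  mean_hr <- if (hr_method == "instantaneous") mean(60000 / v)
             else 60000 / mean(v)
  c(mean_rri = mean(v), mean_hr = mean_hr,
    mean_succ_diff = if (length(v) >= 2) mean(diff(v)) else NA_real_)
}

#' All stationary time-domain indices at once
#'
#' Convenience aggregator over [sdnn], [rmssd], [sdsd], [poincare_sd],
#' [nn50_pnn50] and [mean_indices]. Indices whose minimum length the
#' series does not meet are returned as `NA` rather than raising, so the
#' aggregator can be applied to short analysis windows.
#'
#' @inheritParams nn50_pnn50
#' @inheritParams mean_indices
#' @return A one-row data.frame with columns `n_intervals`, `mean_rri`,
#'   `mean_hr`, `mean_succ_diff`, `sdnn`, `rmssd`, `sdsd`, `sd1`, `sd2`,
#'   `nn50`, `pnn50`.
#' @export
time_domain_indices <- function(rri, denominator = c("n", "n-1"),
                                hr_method = c("instantaneous", "overall")) {
  stopifnot(inherits(rri, "rri_series"))
  n <- length(rri$values)
  out <- data.frame(n_intervals = n, mean_rri = NA_real_,
                    mean_hr = NA_real_, mean_succ_diff = NA_real_,
                    sdnn = NA_real_, rmssd = NA_real_, sdsd = NA_real_,
                    sd1 = NA_real_, sd2 = NA_real_, nn50 = NA_real_,
                    pnn50 = NA_real_)
  if (n >= 1) {
    m <- mean_indices(rri, hr_method = hr_method)
    out$mean_rri <- m[["mean_rri"]]; out$mean_hr <- m[["mean_hr"]]
    out$mean_succ_diff <- m[["mean_succ_diff"]]
  }
  if (n >= 2) {
    out$sdnn <- sdnn(rri); out$rmssd <- rmssd(rri)
    nn <- nn50_pnn50(rri, denominator = denominator)
    out$nn50 <- nn[["nn50"]]; out$pnn50 <- nn[["pnn50"]]
  }
  if (n >= 3) {
    out$sdsd <- sdsd(rri)
    p <- poincare_sd(rri)
    out$sd1 <- p[["sd1"]]; out$sd2 <- p[["sd2"]]
  }
  out
}
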