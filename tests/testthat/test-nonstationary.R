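test_that("time-varying windows partition a constant tachogram", {
  tg <- make_tachogram(121, mean_rri_ms = 1000)
  tv <- time_varying_indices(tg$rri, segment_len_s = 30, overlap_s = 0)
  expect_equal(nrow(tv), 4)
  expect_equal(tv$segment_start_s, c(0, 30, 60, 90))
  expect_true(all(tv$rmssd == 0))
  expect_true(all(tv$mean_rri == 1000))
})

test_that("overlapping windows follow the start-stride arithmetic", {
  tg <- make_tachogram(121, mean_rri_ms = 1000)
  tv <- time_varying_indices(tg$rri, segment_len_s = 30, overlap_s = 15)
  expect_equal(nrow(tv), 7)
  expect_equal(tv$segment_start_s, seq(0, 90, by = 15))
  # bookkeeping: floor((duration - segment) / stride) + 1
  dur <- tg$rri$onset_times[length(tg$rri$values)]
  expect_equal(nrow(tv), floor((dur - 30) / 15) + 1)
  expect_error(time_varying_indices(tg$rri, 30, 30),
               class = "hrvkit_validation")
  expect_error(time_varying_indices(tg$rri, 500),
               class = "hrvkit_insufficient_data")
})

test_that("a whole-record window reproduces the stationary indices", {
  tg <- make_tachogram(200, mean_rri_ms = 850,
                       tones = data.frame(freq_hz = 0.1, amp_ms = 25),
                       noise_sd_ms = 5, seed = 3)
  dur <- tg$rri$onset_times[length(tg$rri$values)]
  tv <- time_varying_indices(tg$rri, segment_len_s = dur)
  st <- time_domain_indices(tg$rri)
  expect_equal(nrow(tv), 1)
  expect_equal(tv$n_beats, length(tg$rri$values))
  for (col in names(st))
    expect_equal(tv[[col]], st[[col]], tolerance = 1e-12)
})

test_that("per-segment RMSSD is stable on a stationary tachogram", {
  tg <- make_tachogram(600, mean_rri_ms = 900,
                       tones = data.frame(freq_hz = c(0.1, 0.25),
                                          amp_ms = c(30, 20)),
                       noise_sd_ms = 3, seed = 21)
  tv <- time_varying_indices(tg$rri, segment_len_s = 30)
  cv <- sd(tv$rmssd) / mean(tv$rmssd)
  expect_lt(cv, 0.3)
})

test_that("time-frequency rows average to the Welch estimate", {
  tg <- make_tachogram(400, mean_rri_ms = 900,
                       tones = data.frame(freq_hz = 0.25, amp_ms = 20),
                       noise_sd_ms = 2, seed = 14)
  tf <- time_frequency_map(tg$rri, method = "welch_segment",
                           segment_len = 256, overlap = 128)
  series <- detrend_polynomial(interpolate_resample(tg$rri, 4), 1)
  w <- welch_psd(series, welch_config(segment_len = 256, shift = 128))
  expect_equal(colMeans(tf$power), w$power, tolerance = 1e-9)
  expect_equal(nrow(tf$power), w$n_segments_averaged)
  # every row's spectral peak sits in the planted HF bin
  peak_bins <- apply(tf$power, 1, which.max)
  expect_equal(length(unique(peak_bins)), 1)
  expect_lte(abs(tf$freqs[peak_bins[1]] - 0.25), tf$freqs[2] - tf$freqs[1])
  expect_true(all(diff(tf$times) > 0))
})

test_that("a chirp-like rising oscillation yields non-decreasing peaks", {
  # oscillation frequency steps 0.1 -> 0.2 -> 0.3 Hz across thirds
  seg_rri <- function(f) {
    make_tachogram(200, mean_rri_ms = 900,
                   tones = data.frame(freq_hz = f, amp_ms = 25))$rri$values
  }
  v <- c(seg_rri(0.1), seg_rri(0.2), seg_rri(0.3))
  rri <- rri_series(v)
  tf <- time_frequency_map(rri, method = "welch_segment",
                           segment_len = 256, overlap = 0)
  peaks <- tf$freqs[apply(tf$power, 1, which.max)]
  df <- tf$freqs[2] - tf$freqs[1]
  expect_true(all(diff(peaks) >= -df))   # one-bin jitter allowed
  expect_gt(peaks[length(peaks)], peaks[1])
})

test_that("AR time-frequency maps report per-segment band powers", {
  tg <- make_tachogram(300, mean_rri_ms = 900,
                       tones = data.frame(freq_hz = 0.25, amp_ms = 20),
                       noise_sd_ms = 2, seed = 5)
  tf <- time_frequency_map(tg$rri, method = "ar", segment_len = 256,
                           overlap = 128, order = 16, padded_len = 512)
  expect_equal(nrow(tf$bands), nrow(tf$power))
  expect_true(all(tf$bands$hf_nu > 70))
  expect_true(all(tf$power >= 0))
})

test_that("exercise-like records show falling then recovering HRV", {
  ex <- make_exercise_tachogram(seed = 11)
  tr <- ex$truth
  tv <- time_varying_indices(ex$rri, 30, 0)
  ramp <- tv[tv$segment_start_s >= tr$pre_end_s &
               tv$segment_end_s <= tr$ramp_end_s, ]
  expect_gt(nrow(ramp), 5)
  expect_true(all(diff(ramp$rmssd) <= 0.1 * head(ramp$rmssd, -1)))
  rec <- tv[tv$segment_start_s >= tr$ramp_end_s + 90, ]
  expect_true(all(diff(rec$rmssd) >= -0.1 * head(rec$rmssd, -1)))
  expect_gt(tail(rec$rmssd, 1), rec$rmssd[1])
})
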