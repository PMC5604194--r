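test_that("segment-count arithmetic follows floor((N - D) / S) + 1", {
  set.seed(2)
  s <- evenly_sampled_series(rnorm(1024), fs = 4)
  w <- welch_psd(s, welch_config(segment_len = 256, shift = 128))
  expect_identical(w$n_segments_averaged, 7L)
  expect_equal(w$freqs[1], 0)
  expect_length(w$power, length(w$freqs))
  expect_true(all(w$power >= 0))
})

test_that("zero and constant signals give zero Welch power", {
  z <- evenly_sampled_series(numeric(512), fs = 4)
  expect_true(all(welch_psd(z)$power == 0))
  const <- evenly_sampled_series(rep(5, 512), fs = 4)
  expect_lt(max(welch_psd(const)$power), 1e-20)
})

test_that("a pure tone's total power is A^2 / 2 (Parseval)", {
  fs <- 4
  t <- (0:1023) / fs
  tone <- evenly_sampled_series(10 * sin(2 * pi * 0.25 * t), fs = fs)
  w <- welch_psd(tone, welch_config(segment_len = 1024, shift = 1024,
                                    window = "rectangular"))
  expect_equal(trapz_total(w), 50, tolerance = 0.02)
})

test_that("rectangular single-segment Welch preserves signal variance", {
  for (seed in 1:30) {
    set.seed(seed)
    x <- rnorm(256, sd = runif(1, 0.5, 20))
    s <- evenly_sampled_series(x, fs = 4)
    w <- welch_psd(s, welch_config(segment_len = 256, shift = 256,
                                   window = "rectangular"))
    expect_equal(trapz_total(w), mean((x - mean(x))^2),
                 tolerance = 0.02)
  }
})

test_that("multi-segment Welch is the mean of per-segment estimates", {
  set.seed(12)
  x <- rnorm(1024)
  s <- evenly_sampled_series(x, fs = 4)
  cfg <- welch_config(segment_len = 256, shift = 128)
  avg <- welch_psd(s, cfg)
  one <- welch_config(segment_len = 256, shift = 256)
  starts <- seq(1, 1024 - 256 + 1, by = 128)
  per <- vapply(starts, function(st)
    welch_psd(evenly_sampled_series(x[st:(st + 255)], fs = 4), one)$power,
    numeric(length(avg$freqs)))
  expect_equal(avg$power, rowMeans(per), tolerance = 1e-9)
})

test_that("zero-padding refines the grid but barely moves band power", {
  set.seed(5)
  s <- evenly_sampled_series(rnorm(512), fs = 4)
  w0 <- welch_psd(s, welch_config(segment_len = 256, shift = 128))
  w1 <- welch_psd(s, welch_config(segment_len = 256, shift = 128,
                                  padded_len = 1024))
  expect_gt(length(w1$freqs), length(w0$freqs))
  b0 <- band_powers(w0)
  b1 <- band_powers(w1)
  expect_equal(b1$tp, b0$tp, tolerance = 0.01)
})

test_that("Burg order-0 estimate of white noise is flat at 2 sigma^2 / fs", {
  set.seed(77)
  sigma <- 3
  s <- evenly_sampled_series(rnorm(4096, sd = sigma), fs = 4)
  b <- burg_psd(s, ar_config(order = 0, padded_len = 256))
  interior <- b$power[b$freqs > 0 & b$freqs < 2]
  expect_equal(unique(round(interior, 10)),
               round(interior[1], 10))  # flat
  expect_equal(interior[1], 2 * sigma^2 / 4, tolerance = 0.05)
})

test_that("Burg recovers AR(2) coefficients and matches ar.burg", {
  ar <- make_ar_process(c(1.2, -0.8), n = 8192, seed = 42, fs = 4)
  fit <- burg_psd(ar, ar_config(order = 2))
  expect_lt(abs(fit$config$a[1] - (-1.2)), 0.05)
  expect_lt(abs(fit$config$a[2] - 0.8), 0.05)
  # independent cross-check: stats::ar.burg in the regression convention
  ref <- stats::ar.burg(ar$values, aic = FALSE, order.max = 2)
  expect_equal(fit$config$a, -ref$ar, tolerance = 1e-3)
  # spectral peak within one grid bin of the AR(2) closed form
  c0 <- -1.2 * (1 - (-0.8)) / (4 * (-0.8))
  f_true <- 4 * acos(c0) / (2 * pi)
  f_hat <- fit$freqs[which.max(fit$power)]
  expect_lte(abs(f_hat - f_true), 4 / 1024)
})

test_that("Burg PSD is sign-invariant, scales quadratically, handles edge cases", {
  set.seed(8)
  x <- as.numeric(arima.sim(list(ar = 0.7), 512))
  s <- evenly_sampled_series(x, fs = 4)
  cfg <- ar_config(order = 8, padded_len = 256)
  p1 <- burg_psd(s, cfg)$power
  expect_equal(burg_psd(evenly_sampled_series(-x, 4), cfg)$power, p1,
               tolerance = 1e-12)
  expect_equal(burg_psd(evenly_sampled_series(3 * x, 4), cfg)$power,
               9 * p1, tolerance = 1e-9)
  expect_error(burg_psd(evenly_sampled_series(rnorm(10), 4),
                        ar_config(order = 10)),
               class = "hrvkit_validation")
  expect_warning(z <- burg_psd(evenly_sampled_series(numeric(64), 4), cfg),
                 "zero variance")
  expect_true(all(z$power == 0))
})

test_that("band integration is exact on flat densities and tiles bands", {
  freqs <- seq(0, 2, by = 0.005)
  flat <- hrvkit:::psd_estimate(freqs, rep(3, length(freqs)), "welch")
  b <- band_powers(flat)
  expect_equal(b$lf, 3 * 0.11, tolerance = 1e-12)
  expect_equal(b$vlf, 3 * 0.04, tolerance = 1e-12)
  expect_equal(b$hf, 3 * 0.25, tolerance = 1e-12)
  expect_equal(b$tp, b$vlf + b$lf + b$hf, tolerance = 1e-12)
  # tiling holds for arbitrary spectra and edges not on the grid
  set.seed(10)
  rough <- hrvkit:::psd_estimate(freqs, rexp(length(freqs)), "welch")
  rb <- band_powers(rough, edges = c(0, 0.0333, 0.1507, 0.4001))
  expect_equal(rb$vlf + rb$lf + rb$hf, rb$tp, tolerance = 1e-9)
  expect_equal(rb$lf_nu + rb$hf_nu, 100, tolerance = 1e-9)
})

test_that("normalized units follow LF / (TP - VLF) * 100", {
  r <- band_ratios(1895.67, 1616.05)
  expect_equal(round(r[["lf_nu"]], 2), 53.98)
  expect_equal(round(r[["hf_nu"]], 2), 46.02)
  expect_equal(round(r[["lf_hf"]], 2), 1.17)
  expect_true(is.na(band_ratios(5, 0)[["lf_hf"]]))
  expect_true(is.na(band_ratios(0, 0, tp = 10, vlf = 10)[["lf_nu"]]))
})

test_that("the full pipeline locates planted LF and HF tones", {
  tg <- make_tachogram(300, mean_rri_ms = 900,
                       tones = data.frame(freq_hz = c(0.1, 0.25),
                                          amp_ms = c(30, 20)))
  fa <- frequency_analysis(tg$rri, method = "welch")
  b <- fa$bands
  expect_gt(b$lf, 0.8 * b$hf)
  expect_gt(b$lf, 10 * b$vlf)
  expect_gt(b$hf, 10 * b$vlf)
  p <- fa$psd
  in_lf <- p$freqs > 0.04 & p$freqs < 0.15
  in_hf <- p$freqs > 0.15 & p$freqs < 0.4
  df <- p$freqs[2] - p$freqs[1]
  expect_lte(abs(p$freqs[in_lf][which.max(p$power[in_lf])] - 0.1), df)
  expect_lte(abs(p$freqs[in_hf][which.max(p$power[in_hf])] - 0.25), df)

  hf_only <- make_tachogram(300, mean_rri_ms = 900,
                            tones = data.frame(freq_hz = 0.25, amp_ms = 20))
  expect_gt(frequency_analysis(hf_only$rri, "welch")$bands$hf_nu, 95)

  const <- make_tachogram(300, mean_rri_ms = 900)
  expect_lt(frequency_analysis(const$rri, "welch")$bands$tp, 1e-6)
})

test_that("the AR pipeline also concentrates power in the planted band", {
  tg <- make_tachogram(300, mean_rri_ms = 900,
                       tones = data.frame(freq_hz = 0.25, amp_ms = 20))
  fa <- frequency_analysis(tg$rri, method = "ar")
  expect_gt(fa$bands$hf_nu, 90)
  expect_equal(fa$psd$method, "ar")
})
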