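# Brute-force time-domain oracles: plain loops over the defining
# formulas, kept deliberately independent of the package's vectorised
# implementations.

oracle_mean <- function(v) {
  s <- 0
  for (x in v) s <- s + x
  s / length(v)
}

oracle_sdnn <- function(v) {
  m <- oracle_mean(v)
  s <- 0
  for (x in v) s <- s + (x - m)^2
  sqrt(s / (length(v) - 1))
}

oracle_rmssd <- function(v) {
  s <- 0
  for (j in 1:(length(v) - 1)) s <- s + (v[j + 1] - v[j])^2
  sqrt(s / (length(v) - 1))
}

oracle_succ_diffs <- function(v) {
  d <- numeric(length(v) - 1)
  for (j in 1:(length(v) - 1)) d[j] <- v[j + 1] - v[j]
  d
}

oracle_sdsd <- function(v) oracle_sdnn_like(oracle_succ_diffs(v))

# sample sd of an arbitrary vector, loop form
oracle_sdnn_like <- function(d) {
  m <- oracle_mean(d)
  s <- 0
  for (x in d) s <- s + (x - m)^2
  sqrt(s / (length(d) - 1))
}

oracle_sd1_sd2 <- function(v) {
  sdsd <- oracle_sdsd(v)
  sdnn <- oracle_sdnn(v)
  c(sd1 = sdsd / sqrt(2), sd2 = sqrt(max(0, 2 * sdnn^2 - sdsd^2 / 2)))
}

oracle_nn50 <- function(v) {
  cnt <- 0
  for (j in 1:(length(v) - 1)) if (abs(v[j + 1] - v[j]) > 50) cnt <- cnt + 1
  c(nn50 = cnt, pnn50 = 100 * cnt / length(v))
}

oracle_mean_hr <- function(v) {
  s <- 0
  for (x in v) s <- s + 60000 / x
  s / length(v)
}

# deterministic random RRi series for property loops
random_rri <- function(n, seed) {
  set.seed(seed)
  rri_series(runif(n, 400, 1400))
}

# trapezoidal total power of a PSD estimate over its full grid
trapz_total <- function(psd) {
  f <- psd$freqs
  p <- psd$power
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}
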