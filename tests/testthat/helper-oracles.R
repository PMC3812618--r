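# Shared oracles and fixtures, all built in code.

# Brute-force orthogonality index: explicit double loop over distinct
# component pairs, independent of the vectorized implementation.
io_brute_force <- function(comps, x) {
  total <- 0
  m <- ncol(comps)
  for (j in seq_len(m)) {
    for (k in seq_len(m)) {
      if (j != k) total <- total + sum(comps[, j] * comps[, k])
    }
  }
  total / sum(x^2)
}

# Direct population-moment Pearson coefficient (Eq.-style oracle).
pearson_brute_force <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y))) /
    (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
}

# Two-sided correlation p-value by numeric integration of the t density,
# independent of stats::pt.
p_value_by_integration <- function(rho, n) {
  df <- n - 2
  tt <- abs(rho) * sqrt(df / (1 - rho^2))
  log_norm <- lgamma((df + 1) / 2) - lgamma(df / 2) - log(sqrt(df * pi))
  dens <- function(u) {
    exp(log_norm - (df + 1) / 2 * log1p(u^2 / df))
  }
  2 * stats::integrate(dens, tt, Inf, rel.tol = 1e-12)$value
}

band_energy <- function(x, low, high, rate) {
  sum(bandpass_filter(x, low, high, rate)^2)
}

# Energy above `cut_hz` of a possibly drifting path: detrend, Hann-taper,
# integrate the periodogram above the cut.
highfreq_energy <- function(v, cut_hz, rate) {
  n <- length(v)
  t <- seq_len(n)
  v <- v - stats::fitted(stats::lm(v ~ t))
  v <- v * (0.5 - 0.5 * cos(2 * pi * (t - 1) / (n - 1)))
  f <- (0:(n - 1)) * rate / n
  f <- pmin(f, rate - f)
  s <- Mod(stats::fft(v))^2
  sum(s[f > cut_hz])
}

# Fraction of the band-limited artifact component surviving in a signal,
# by least-squares projection onto the known component.
artifact_attenuation <- function(output, input, artifact, low, high, rate) {
  a <- bandpass_filter(artifact, low, high, rate)
  c_out <- sum(bandpass_filter(output, low, high, rate) * a) / sum(a^2)
  c_in <- sum(bandpass_filter(input, low, high, rate) * a) / sum(a^2)
  (c_out / c_in)^2
}

# Peak-amplitude retention of each blink event on one channel.
blink_retention <- function(clean_channel, blink_component, peak_times,
                            rate) {
  first_peaks <- peak_times[seq(1, length(peak_times), by = 2)]
  vapply(first_peaks, function(pk) {
    idx <- max(1, round((pk - 0.1) * rate)):round((pk + 0.1) * rate)
    max(abs(clean_channel[idx])) / max(abs(blink_component[idx]))
  }, numeric(1))
}

# Small multichannel fixture: shared sinusoid + independent noise on k
# channels, decomposed per channel.
shared_tone_decompositions <- function(n_channels = 4, n = 640, rate = 128,
                                       tone_hz = 2, tone_amp = 8,
                                       noise_sd = 1, seed = 1) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / rate
  labs <- paste0("CH", seq_len(n_channels))
  decs <- lapply(seq_len(n_channels), function(i) {
    emd(tone_amp * sin(2 * pi * tone_hz * t) + rnorm(n, sd = noise_sd))
  })
  names(decs) <- labs
  decs
}
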