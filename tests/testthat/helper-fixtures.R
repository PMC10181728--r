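# Shared fixtures and independent oracles, built in code at test time.

# Compact simulated measurement; overrides forwarded to sim_config().
quick_sim <- function(duration_s = 120, seed = 1, ...) {
  simulate_measurement(sim_config(duration_s = duration_s, seed = seed, ...))
}

# Clean single-channel fixture with constant rates and no disturbances;
# any named override in ... wins over the clean defaults.
clean_sim <- function(duration_s = 120, hr = 150, rr = 45, seed = 1, ...) {
  args <- modifyList(list(duration_s = duration_s, seed = seed,
                          hr_bpm = hr, rr_bpm = rr,
                          mayer_amp = 0, drift_amp = 0, noise_sd = 0,
                          artifact_rate = 0, channel_scales = 1),
                     list(...))
  do.call(quick_sim, args)
}

# Plain zero-padded periodogram peak: the FFT oracle used against the
# spectral machinery. Independent of multitaper_psd.
periodogram_peak <- function(x, fs, flo, fhi, nfft = 2^ceiling(log2(8 * length(x)))) {
  X <- fft(c(x - mean(x), rep(0, nfft - length(x))))
  fr <- (seq_len(nfft) - 1) * fs / nfft
  sel <- fr >= flo & fr <= fhi & fr <= fs / 2
  fr[sel][which.max(Mod(X[sel])^2)]
}

# Brute-force argmax over the grid points of a spectrum: re-implements the
# band search as an explicit loop.
brute_band_argmax <- function(s, lo, hi) {
  best_f <- NA_real_
  best_p <- -Inf
  for (i in seq_along(s$freqs)) {
    f <- s$freqs[i]
    if (f >= lo && f <= hi && s$power[i] > best_p) {
      best_p <- s$power[i]
      best_f <- f
    }
  }
  best_f
}

# Brute-force top-k frequency average on a resampled in-band grid.
brute_topk_avg <- function(s, lo, hi, n_grid, topk) {
  grid <- seq(lo, hi, length.out = n_grid)
  pw <- numeric(n_grid)
  for (i in seq_len(n_grid))
    pw[i] <- approx(s$freqs, s$power, xout = grid[i])$y
  ord <- order(pw, decreasing = TRUE)
  mean(grid[ord[seq_len(topk)]])
}

# Least-squares amplitude of a sinusoid component at frequency f.
sine_amplitude <- function(x, fs, f) {
  t <- (seq_along(x) - 1) / fs
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  cf <- lm.fit(X, x - mean(x))$coefficients
  sqrt(sum(cf^2))
}

expect_rows <- function(df, n) expect_identical(nrow(df), as.integer(n))

next_pow2_ <- function(n) 2^ceiling(log2(n))
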