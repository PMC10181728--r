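fs <- 100

test_that("the adaptive hr band brackets a clean cardiac line", {
  set.seed(1)
  t <- (0:(120 * fs - 1)) / fs
  # Noise weak enough that the top-50 components all sit on the spectral
  # skirt of the cardiac line, symmetric about it.
  x <- sin(2 * pi * 2.2 * t) + 1e-4 * rnorm(length(t))
  b <- estimate_hr_band(x, fs)
  avg <- attr(b, "avg_freq")
  expect_equal(avg, 2.2, tolerance = 0.1)
  expect_equal(b$hi - b$lo, 1.0, tolerance = 1e-12)
  # Brute-force top-50 oracle on the same spectrum.
  hp <- moving_average_highpass(x, fs, 1)
  sp <- multitaper_psd(hp, fs)
  expect_equal(avg, brute_topk_avg(sp, 1.25, 3.5, 100, 50), tolerance = 1e-9)
})

test_that("white noise centres the hr band near the band midpoint", {
  avgs <- vapply(1:20, function(s) {
    set.seed(s)
    attr(estimate_hr_band(rnorm(90 * fs), fs), "avg_freq")
  }, 0)
  expect_equal(mean(avgs), (1.25 + 3.5) / 2, tolerance = 0.1)
})

test_that("iqr series matches a brute-force windowed oracle", {
  sim <- quick_sim(duration_s = 60, seed = 2)
  x <- thb(sim$recording)
  iqr <- compute_iqr_series(x, fs)
  expect_length(iqr$values, length(x))
  expect_true(all(iqr$values >= 0))
  # Brute-force IQR at a few window centres (1-s windows, 0.5-s hop).
  for (w in c(0, 10, 57)) {
    idx <- (w * 50 + 1):(w * 50 + 100)
    q <- unname(quantile(x[idx], c(0.25, 0.75)))
    centre_sample <- round(w * 50 + 1 + 49.5)
    expect_equal(iqr$values[centre_sample] * iqr$normalizer, q[2] - q[1],
                 tolerance = 0.02)
  }
  expect_equal(iqr$normalizer, abs(median(x)))
})

test_that("constant input gives a zero iqr series and a warning-free run", {
  iqr <- compute_iqr_series(rep(5, 1000), fs)
  expect_true(all(iqr$values == 0))
  # Near-zero median triggers the epsilon substitution with a warning.
  set.seed(3)
  expect_warning(compute_iqr_series(rnorm(1000, sd = 1e-9), fs), "normalizer")
})

test_that("windowed iqr of uniform noise approaches the theoretical 0.5", {
  set.seed(4)
  x <- runif(600 * fs)                      # uniform on [0, 1]
  iqr <- compute_iqr_series(x, fs)
  expect_equal(mean(iqr$values * iqr$normalizer), 0.5, tolerance = 0.02)
})

test_that("an injected burst lifts the iqr at least fivefold", {
  sim <- clean_sim(duration_s = 60, seed = 5, noise_sd = 0.05)
  x <- thb(sim$recording)
  idx <- (10 * fs + 1):(12 * fs)
  x[idx] <- x[idx] + 10 * 0.25 * sin(2 * pi * 7 * seq_along(idx) / fs)
  iqr <- compute_iqr_series(x, fs)
  expect_gt(min(iqr$values[(10.2 * fs):(11.8 * fs)]),
            5 * median(iqr$values))
})

test_that("segmentation follows the 30 s / 7.5 s half-open grid", {
  p <- nrr_params()
  seg30 <- segment_measurement(numeric(30 * fs), NULL, fs, p)
  expect_length(seg30, 1L)
  seg60 <- segment_measurement(numeric(60 * fs), NULL, fs, p)
  expect_length(seg60, 5L)                  # floor((60-30)/7.5)+1
  starts <- vapply(seg60, `[[`, 0, "start_s")
  expect_equal(diff(starts), rep(7.5, 4))
  # Exact count formula across assorted durations.
  for (T in c(30, 37.5, 52, 61, 95.2, 240)) {
    n_seg <- length(segment_measurement(numeric(round(T * fs)), NULL, fs, p))
    expect_identical(n_seg, as.integer(floor((T - 30) / 7.5) + 1))
  }
  expect_error(segment_measurement(numeric(100), NULL, fs, p), "shorter")
})

test_that("motion gate thresholds strictly and includes at exactly 50%", {
  p <- nrr_params()
  n <- 3000
  all_clean <- motion_gate(numeric(n), p)
  expect_equal(all_clean$clean_frac, 1)
  expect_true(all_clean$included)
  # 60% of samples at/above threshold -> 40% clean -> dismissed.
  g40 <- motion_gate(c(rep(0, 0.4 * n), rep(0.02, 0.6 * n)), p)
  expect_equal(g40$clean_frac, 0.4)
  expect_false(g40$included)
  # Exactly 50% clean -> included (dismissal is strictly below 50%).
  g50 <- motion_gate(c(rep(0, n / 2), rep(0.02, n / 2)), p)
  expect_equal(g50$clean_frac, 0.5)
  expect_true(g50$included)
  # Values exactly at the threshold are artifact (strict "<").
  gthr <- motion_gate(rep(p$iqr_threshold, n), p)
  expect_equal(gthr$clean_frac, 0)
})

test_that("lowering the iqr threshold never increases the clean fraction", {
  set.seed(6)
  slice <- abs(rnorm(3000, sd = 0.01))
  cf <- vapply(c(0.02, 0.01, 0.005, 0.002), function(th)
    motion_gate(slice, nrr_params(iqr_threshold = th))$clean_frac, 0)
  expect_true(all(diff(cf) <= 0))
})

test_that("hr per segment survives trends and partial masking", {
  p <- nrr_params()
  t <- (0:(30 * fs - 1)) / fs
  x <- sin(2 * pi * 2 * t)
  b <- band(1.5, 2.5)
  hr <- compute_hr(x, rep(1, length(x)), b, fs, p)
  step_bpm <- 60 * fs / next_pow2_(8 * length(x))
  expect_lt(abs(hr - 120), step_bpm + 1e-9)
  # A strong linear trend changes nothing (least-squares detrend).
  hr_tr <- compute_hr(x + 5 * t, rep(1, length(x)), b, fs, p)
  expect_equal(hr_tr, hr)
  # Masking out a 40% artifact stretch moves HR by < 2 BPM.
  mask <- rep(1, length(x)); mask[1:(0.4 * length(x))] <- 0
  x_art <- x; x_art[mask == 0] <- x_art[mask == 0] + rnorm(sum(mask == 0), 0, 5)
  hr_mask <- compute_hr(x_art, mask, b, fs, p)
  expect_lt(abs(hr_mask - hr), 2)
})

test_that("rr band construction follows the adaptive-band arithmetic", {
  p <- nrr_params()
  t <- (0:(30 * fs - 1)) / fs
  conv <- 0.15 * sin(2 * pi * 0.8 * t) + 0.25 * sin(2 * pi * 2.33 * t)
  out <- compute_rr(conv, 140, fs, p)
  # HR = 140 BPM -> band (0.35, 1.983) Hz, upper edge clipped at 2 Hz rule.
  expect_equal(out$band_rr$lo, 0.15 * 140 / 60)
  expect_equal(out$band_rr$hi, min(0.85 * 140 / 60, 2))
  expect_lt(abs(out$rr_bpm - 48), 2.1)      # within the spectral-window width
  # Whenever a_high*hr <= bpf_hi the edge ratio equals a_low/a_high.
  out2 <- compute_rr(conv, 120, fs, p)
  expect_equal(out2$band_rr$lo / out2$band_rr$hi, p$a_low / p$a_high,
               tolerance = 1e-12)
})

test_that("rr error is bounded by the spectral-window width at any phase", {
  # The multitaper spectral window is flat-topped over roughly +/- NW/T
  # (0.083 Hz for 30 s), so the in-band argmax can land on a ripple crest
  # up to ~0.07 Hz (~4 BPM) from a pure line depending on segment phase.
  # The error never exceeds that window half-width.
  p <- nrr_params()
  t <- (0:(30 * fs - 1)) / fs
  for (ph in seq(0, 2 * pi, length.out = 9)) {
    out <- compute_rr(0.15 * sin(2 * pi * 0.8 * t + ph), 140, fs, p)
    expect_lt(abs(out$rr_bpm - 48), 60 * 0.075)
  }
})

test_that("full pipeline recovers constant rates and scale invariance holds", {
  sim <- clean_sim(duration_s = 120, hr = 150, rr = 48, seed = 7,
                   noise_sd = 0.02)
  res <- run_nrr(sim$recording)
  expect_true(all(res$included))
  expect_true(all(abs(res$rr_bpm - 48) < 4.5))   # spectral-window bound
  expect_true(all(abs(res$hr_bpm - 150) < 2.1))
  # Scale invariance: a positive gain leaves the outputs unchanged.
  rec2 <- sim$recording
  for (lb in names(rec2$data)) rec2$data[[lb]] <- 3.7 * rec2$data[[lb]]
  res2 <- run_nrr(rec2)
  expect_equal(res2$rr_bpm, res$rr_bpm)
  expect_equal(res2$hr_bpm, res$hr_bpm)
  expect_equal(res2$clean_frac, res$clean_frac)
})

test_that("low-quality measurements raise the excluded-measurement signal", {
  set.seed(8)
  n <- 90 * fs
  noise <- recording(fs, list(ch1_O2Hb = rnorm(n, 30), ch1_HHb = rnorm(n, 30)))
  expect_error(run_nrr(noise), class = "nrr_excluded_measurement")
})

test_that("continuous artifact dismisses every segment", {
  sim <- quick_sim(duration_s = 90, seed = 9, artifact_rate = 60,
                   artifact_duration_s = 5, channel_scales = 1)
  res <- run_nrr(sim$recording, channel = "ch1")
  expect_true(all(!res$included))
  expect_true(all(is.na(res$rr_bpm)))
})
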