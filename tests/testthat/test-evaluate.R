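mk_results <- function(start_s, rr, included = TRUE) {
  df <- data.frame(method = "nrr", start_s = start_s,
                   included = included, clean_frac = 1,
                   hr_bpm = 140, rr_bpm = rr,
                   band_rr_lo = 0.35, band_rr_hi = 1.98)
  attr(df, "params") <- nrr_params()
  class(df) <- c("nrr_results", "data.frame")
  df
}

test_that("reference alignment averages 15 samples per 30-s segment", {
  ref <- reference_rr(rep(50, 120), fs_ref = 0.5)   # 4 min of constant 50
  res <- mk_results(seq(0, 90, by = 7.5), 48)
  pr <- align_reference(ref, res)
  expect_rows(pr, 13)
  expect_true(all(pr$ref_rr == 50))
  # Linearly rising reference: the paired value equals the arithmetic
  # mean of the 15 in-window samples.
  rr_lin <- seq(40, 60, length.out = 120)
  ref2 <- reference_rr(rr_lin, fs_ref = 0.5)
  pr2 <- align_reference(ref2, mk_results(0, 48))
  expect_equal(pr2$ref_rr, mean(rr_lin[1:15]))
  expect_identical(sum(ref_times(ref2) >= 0 & ref_times(ref2) < 30), 15L)
})

test_that("segments with no reference coverage are dropped and counted", {
  rr <- rep(50, 120)
  rr[1:15] <- NA                          # first segment entirely gapped
  ref <- reference_rr(rr, fs_ref = 0.5)
  res <- mk_results(c(0, 30, 60), 48)
  pr <- align_reference(ref, res)
  expect_rows(pr, 2)
  expect_identical(attr(pr, "n_dropped"), 1L)
  # Excluded segments never pair.
  res2 <- mk_results(c(0, 30, 60), 48, included = c(FALSE, TRUE, TRUE))
  res2$rr_bpm[1] <- NA
  expect_identical(attr(align_reference(ref, res2), "n_included"), 2L)
})

test_that("agreement reproduces the closed-form metrics", {
  mk_pairs <- function(ref, est) {
    df <- data.frame(start_s = seq_along(ref), ref_rr = ref, est_rr = est)
    attr(df, "n_total") <- length(ref)
    attr(df, "n_included") <- length(ref)
    df
  }
  # Zero error vector.
  ag0 <- agreement(mk_pairs(c(40, 50, 60), c(40, 50, 60)))
  expect_equal(ag0$me, 0)
  expect_equal(ag0$rmse, 0)
  expect_equal(ag0$loa, 0)
  expect_equal(ag0$pearson_r, 1)
  expect_lt(ag0$pearson_p, 0.01)
  expect_equal(ag0$included_pct, 100)
  # Errors {+1, -1, +1, -1}: ME 0, RMSE 1, LoA 1.96 * sd.
  ref <- c(40, 45, 50, 55)
  ag1 <- agreement(mk_pairs(ref, ref + c(1, -1, 1, -1)))
  expect_equal(ag1$me, 0, tolerance = 1e-12)
  expect_equal(ag1$rmse, 1, tolerance = 1e-12)
  expect_equal(ag1$loa, 1.96 * sd(c(1, -1, 1, -1)), tolerance = 1e-12)
  # Two-point error vector {+1, -1} has sample sd sqrt(2).
  ag2 <- agreement(mk_pairs(c(40, 50, 60), c(41, 49, 60)))
  expect_equal(ag2$loa, 1.96 * sd(c(1, -1, 0)), tolerance = 1e-12)
  # RMSE^2 = ME^2 + ((n-1)/n) sd^2 identity.
  set.seed(1)
  est <- ref + rnorm(4)
  ag3 <- agreement(mk_pairs(ref, est))
  err <- est - ref
  expect_equal(ag3$rmse^2, ag3$me^2 + (3 / 4) * var(err), tolerance = 1e-10)
  # Zero-variance series: r reported as NA, not 0.
  agc <- agreement(mk_pairs(c(50, 50, 50), c(51, 49, 50)))
  expect_true(is.na(agc$pearson_r))
})

test_that("agreement transforms as expected under shifts and scalings", {
  df <- data.frame(start_s = 1:20, ref_rr = seq(30, 68, by = 2))
  set.seed(2)
  df$est_rr <- df$ref_rr + rnorm(20, 0.5, 1.5)
  base <- agreement(df, n_total = 20)
  shift <- df; shift$ref_rr <- shift$ref_rr + 7; shift$est_rr <- shift$est_rr + 7
  ag_s <- agreement(shift, n_total = 20)
  expect_equal(ag_s$me, base$me, tolerance = 1e-12)
  expect_equal(ag_s$rmse, base$rmse, tolerance = 1e-12)
  expect_equal(ag_s$loa, base$loa, tolerance = 1e-12)
  scl <- df; scl$ref_rr <- 3 * scl$ref_rr; scl$est_rr <- 3 * scl$est_rr
  ag_k <- agreement(scl, n_total = 20)
  expect_equal(ag_k$me, 3 * base$me, tolerance = 1e-12)
  expect_equal(ag_k$rmse, 3 * base$rmse, tolerance = 1e-12)
  expect_equal(ag_k$pearson_r, base$pearson_r, tolerance = 1e-12)
})

test_that("the 30% boundary matches hand arithmetic", {
  mk <- function(ref, est) data.frame(start_s = 1, ref_rr = ref, est_rr = est)
  expect_equal(boundary30(mk(50, 50))$pct_outside, 0)
  expect_equal(boundary30(mk(50, 70))$pct_outside, 100)   # |20| >= 18
  expect_equal(boundary30(mk(50, 65))$pct_outside, 0)     # |15| < 17.25
  # Decisions invariant under common positive rescaling of a pair.
  expect_equal(boundary30(mk(50 * 3, 70 * 3))$outside,
               boundary30(mk(50, 70))$outside)
})

test_that("method comparison flags a constant offset and respects pairing", {
  set.seed(3)
  n <- 40
  ref <- runif(n, 35, 65)
  a <- data.frame(start_s = 1:n, ref_rr = ref, est_rr = ref + rnorm(n, 0, 1))
  b <- data.frame(start_s = 1:n, ref_rr = ref,
                  est_rr = ref + rnorm(n, 5, 1))   # ~5 BPM worse
  cmp <- compare_methods(list(nrr = a, bpf = b))
  expect_rows(cmp, 1)
  expect_lt(cmp$p_value, 0.05)
  # Closed-form check: paired t statistic on the |error| differences.
  d <- abs(a$est_rr - a$ref_rr) - abs(b$est_rr - b$ref_rr)
  t_hand <- mean(d) / (sd(d) / sqrt(n))
  p_hand <- 2 * pt(-abs(t_hand), n - 1)
  expect_equal(cmp$p_value, p_hand, tolerance = 1e-12)
  # Self-comparison is defined as non-significant.
  self <- compare_methods(list(a = a, b = a))
  expect_equal(self$p_value, 1)
  # Jointly permuting segment order changes nothing.
  perm <- sample(n)
  cmp_p <- compare_methods(list(nrr = a[perm, ], bpf = b[perm, ]))
  expect_equal(cmp_p$p_value, cmp$p_value, tolerance = 1e-12)
  # Three methods -> three pairs.
  cmp3 <- compare_methods(list(nrr = a, bpf = b, bw = b))
  expect_rows(cmp3, 3)
})

test_that("sensitivity sweep returns the single cell of a trivial grid", {
  sims <- lapply(1:2, function(s)
    c(clean_sim(duration_s = 90, seed = s, noise_sd = 0.02),
      list(channel = "ch1")))
  out <- sensitivity_grid(sims, win_grid = 30, alow_grid = 0.15,
                          ahigh_grid = 0.85)
  expect_equal(out$optimum$seg_len_s, 30)
  expect_equal(out$optimum$a_low, 0.15)
  expect_equal(out$optimum$a_high, 0.85)
  expect_rows(out$window, 1)
})

test_that("sensitivity ties prefer the larger adaptive band", {
  # Force exact ties by a dataset on which RMSE is flat across the axis:
  # clean fixtures give identical RMSEs for neighbouring a_low values.
  sims <- lapply(1:2, function(s)
    c(clean_sim(duration_s = 90, seed = s, rr = 48, noise_sd = 0.02),
      list(channel = "ch1")))
  out <- sensitivity_grid(sims, win_grid = 30,
                          alow_grid = c(0.15, 0.20),
                          ahigh_grid = c(0.80, 0.85))
  # Both a_low cells tie (p >= alpha) -> the lower one is selected;
  # both a_high cells tie -> the higher one.
  expect_equal(out$optimum$a_low, 0.15)
  expect_equal(out$optimum$a_high, 0.85)
})
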