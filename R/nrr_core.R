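#' Parameters of the NRR extraction algorithm
#'
#' Defaults follow the published configuration: 30-s windows with 75%
#' overlap (7.5-s hop), a 1-s sliding IQR thresholded at 1% with a 50%
#' clean-sample inclusion rule, a predefined cardiac search band of
#' 1.25-3.5 Hz (75-210 BPM), a +/-0.5 Hz adaptive HR band around the
#' top-50 average frequency, a band-pass of [0.1*HR, 2] Hz ahead of RR
#' estimation, and an adaptive RR band of [0.15*HR, 0.85*HR].
#'
#' @param seg_len_s segment length, seconds.
#' @param overlap_frac segment overlap fraction.
#' @param iqr_win_s IQR sliding-window length, seconds.
#' @param iqr_threshold motion threshold on the normalized IQR.
#' @param clean_min_frac minimum clean fraction for segment inclusion.
#' @param hr_band_lo,hr_band_hi predefined cardiac band, Hz.
#' @param hr_halfwidth half-width of the adaptive HR band, Hz.
#' @param topk_components number of sorted components averaged.
#' @param grid_components_in_band resampled component count in the band.
#' @param bpf_lo_factor lower band-pass cutoff as a fraction of HR.
#' @param bpf_hi upper band-pass cutoff, Hz.
#' @param a_low,a_high adaptive RR band as fractions of HR.
#' @param nw,k multitaper time-bandwidth and taper count.
#' @param nfft_factor zero-padding factor for segment spectra.
#' @param kaiser_atten_db,kaiser_trans_hz Kaiser design targets.
#' @param norm_eps floor on the |median(tHb)| IQR normalizer.
#' @return an object of class `nrr_params`.
#' @export
nrr_params <- function(seg_len_s = 30, overlap_frac = 0.75,
                       iqr_win_s = 1, iqr_threshold = 0.01,
                       clean_min_frac = 0.5,
                       hr_band_lo = 1.25, hr_band_hi = 3.5,
                       hr_halfwidth = 0.5, topk_components = 50,
                       grid_components_in_band = 100,
                       bpf_lo_factor = 0.1, bpf_hi = 2.0,
                       a_low = 0.15, a_high = 0.85,
                       nw = 2.5, k = 5, nfft_factor = 8,
                       kaiser_atten_db = 50, kaiser_trans_hz = 0.1,
                       norm_eps = 1e-6) {
  p <- structure(as.list(environment()), class = "nrr_params")
  stopifnot(p$a_low > 0, p$a_low < p$a_high, p$a_high < 1,
            p$overlap_frac > 0, p$overlap_frac < 1,
            p$hr_band_lo < p$hr_band_hi,
            p$iqr_threshold > 0, p$iqr_threshold < 1,
            p$clean_min_frac > 0, p$clean_min_frac < 1)
  p
}

hop_s <- function(p) p$seg_len_s * (1 - p$overlap_frac)

#' Estimate the per-measurement heart-rate frequency band
#'
#' High-passes tHb by subtracting a 1-s moving average, computes the
#' multitaper spectrum of the whole measurement, resamples it onto
#' exactly `grid_components_in_band` uniform frequencies inside the
#' predefined cardiac band, averages the frequencies of the
#' `topk_components` strongest components, and returns that average
#' +/- `hr_halfwidth` Hz (kept inside (0, fs/2)).
#'
#' @param x tHb series, at least 60 s.
#' @param fs sampling rate, Hz.
#' @param p an [nrr_params()] object.
#' @return an `nrr_band` with attribute `avg_freq`.
#' @export
estimate_hr_band <- function(x, fs, p = nrr_params()) {
  if (length(x) < 60 * fs) stop("need at least 60 s of signal")
  hp <- moving_average_highpass(x, fs, p$iqr_win_s)
  sp <- multitaper_psd(hp, fs, nw = p$nw, k = p$k, nfft_factor = p$nfft_factor)
  grid <- seq(p$hr_band_lo, p$hr_band_hi,
              length.out = p$grid_components_in_band)
  pw <- approx(sp$freqs, sp$power, xout = grid)$y
  if (all(pw <= 0)) stop("no spectral power inside the cardiac band")
  top <- order(pw, decreasing = TRUE)[seq_len(p$topk_components)]
  avg <- mean(grid[top])
  b <- band(max(avg - p$hr_halfwidth, 1e-9),
            min(avg + p$hr_halfwidth, fs / 2 - 1e-9))
  attr(b, "avg_freq") <- avg
  b
}

#' Normalized sliding-window IQR of a tHb series
#'
#' Computes the interquartile range in 1-s windows hopped by half a
#' window, cubic-interpolates the window-centre values back to the
#' signal rate (edges held at the nearest computed value), and divides
#' by |median(tHb)| floored at `norm_eps`.
#'
#' @param x tHb series, at least two windows long.
#' @param fs sampling rate, Hz.
#' @param p an [nrr_params()] object.
#' @return an object of class `nrr_iqr`: list with `values` (same length
#'   as `x`), `normalizer`, `fs`.
#' @export
compute_iqr_series <- function(x, fs, p = nrr_params()) {
  n <- length(x)
  if (n < 2 * p$iqr_win_s * fs) stop("need at least 2 s of signal")
  L <- round(p$iqr_win_s * fs)
  hop <- max(1L, round(L / 2))
  starts <- seq(1L, n - L + 1L, by = hop)
  vals <- vapply(starts, function(s0) {
    q <- quantile(x[s0:(s0 + L - 1L)], c(0.25, 0.75), names = FALSE)
    q[2] - q[1]
  }, 0)
  centers <- (starts - 1 + (L - 1) / 2) / fs
  tt <- pmin(pmax((seq_len(n) - 1) / fs, centers[1]), centers[length(centers)])
  iq <- spline(centers, vals, xout = tt)$y
  iq[iq < 0] <- 0
  normalizer <- abs(median(x))
  if (normalizer < p$norm_eps) {
    warning("degenerate IQR normalizer |median(tHb)| < ", p$norm_eps,
            "; substituting the epsilon floor")
    normalizer <- p$norm_eps
  }
  structure(list(values = iq / normalizer, normalizer = normalizer, fs = fs),
            class = "nrr_iqr")
}

#' Segment a measurement into overlapping windows
#'
#' Half-open windows `[k*hop, k*hop + seg_len)` seconds; the trailing
#' partial window is dropped, so the count is
#' `floor((T - seg_len)/hop) + 1`.
#'
#' @param x tHb series, at least one segment long.
#' @param iqr an `nrr_iqr` aligned with `x` (optional).
#' @param fs sampling rate, Hz.
#' @param p an [nrr_params()] object.
#' @return list of lists with `start_s`, `thb` and (if given) `iqr` slices.
#' @export
segment_measurement <- function(x, iqr = NULL, fs, p = nrr_params()) {
  n <- length(x)
  L <- round(p$seg_len_s * fs)
  if (n < L) stop("signal shorter than one segment")
  hop <- hop_s(p) * fs
  starts <- round(seq(0, n - L, by = hop))
  lapply(starts, function(s0) {
    idx <- (s0 + 1):(s0 + L)
    out <- list(start_s = s0 / fs, thb = x[idx])
    if (!is.null(iqr)) out$iqr <- iqr$values[idx]
    out
  })
}

#' Motion-artifact gate for one segment
#'
#' The binary mask is one where the normalized IQR is strictly below the
#' threshold (presumed artifact-free). The segment is included when the
#' clean fraction is at least `clean_min_frac`; dismissal is strict
#' ("less than 50%"), so exactly 50% clean is kept.
#'
#' @param iqr_slice normalized IQR values of the segment.
#' @param p an [nrr_params()] object.
#' @return list with `mask`, `clean_frac`, `included`.
#' @export
motion_gate <- function(iqr_slice, p = nrr_params()) {
  mask <- as.numeric(iqr_slice < p$iqr_threshold)
  cf <- mean(mask)
  list(mask = mask, clean_frac = cf, included = cf >= p$clean_min_frac)
}

linear_detrend <- function(x) {
  n <- length(x)
  tt <- seq_len(n)
  fit <- lm.fit(cbind(1, tt), x)
  x - fit$fitted.values
}

# Detrended, mask-multiplied segment: the "converted" tHb of Stage B.
convert_segment <- function(thb_slice, mask) linear_detrend(thb_slice) * mask

#' Heart rate of one segment
#'
#' Linear-detrends the segment, multiplies by the motion mask (artifact
#' samples become zero), and returns 60 times the dominant multitaper
#' frequency inside the adaptive HR band.
#'
#' @param thb_slice tHb segment.
#' @param mask binary motion mask from [motion_gate()].
#' @param band_hr an `nrr_band` from [estimate_hr_band()].
#' @param fs sampling rate, Hz.
#' @param p an [nrr_params()] object.
#' @return HR in BPM.
#' @export
compute_hr <- function(thb_slice, mask, band_hr, fs, p = nrr_params()) {
  conv <- convert_segment(thb_slice, mask)
  sp <- multitaper_psd(conv, fs, nw = p$nw, k = p$k,
                       nfft_factor = p$nfft_factor)
  sel <- sp$freqs >= band_hr$lo & sp$freqs <= band_hr$hi
  if (all(sp$power[sel] <= 0)) stop("zero spectral power in the HR band")
  60 * dominant_frequency(sp, band_hr)
}

#' Respiratory rate of one segment
#'
#' Band-passes the converted (detrended, masked) segment with a
#' zero-phase Kaiser FIR between `bpf_lo_factor * HR` and `bpf_hi` Hz,
#' then returns 60 times the dominant multitaper frequency inside the
#' adaptive RR band `[a_low*HR, min(a_high*HR, bpf_hi)]` Hz.
#'
#' @param conv_slice converted tHb segment (detrended and masked).
#' @param hr_bpm heart rate of the segment, BPM.
#' @param fs sampling rate, Hz.
#' @param p an [nrr_params()] object.
#' @return list with `rr_bpm` and `band_rr` (`nrr_band`).
#' @export
compute_rr <- function(conv_slice, hr_bpm, fs, p = nrr_params()) {
  hr_hz <- hr_bpm / 60
  filt <- kaiser_bandpass_zerophase(conv_slice, fs,
                                    lo = p$bpf_lo_factor * hr_hz,
                                    hi = p$bpf_hi,
                                    atten_db = p$kaiser_atten_db,
                                    trans_hz = p$kaiser_trans_hz)
  sp <- multitaper_psd(filt, fs, nw = p$nw, k = p$k,
                       nfft_factor = p$nfft_factor)
  b <- band(p$a_low * hr_hz, min(p$a_high * hr_hz, p$bpf_hi))
  list(rr_bpm = 60 * dominant_frequency(sp, b), band_rr = b)
}

excluded_measurement <- function(msg, low_frac) {
  stop(structure(class = c("nrr_excluded_measurement", "error", "condition"),
                 list(message = paste0(msg, " (", round(100 * low_frac, 1),
                                       "% of SQI windows below level 2)"),
                      call = NULL)))
}

#' Run the full NRR extraction on a recording
#'
#' Stage A (once per measurement): channel selection by SQI with the
#' 75% exclusion rule, the adaptive HR band, the normalized IQR series,
#' and segmentation into 30-s windows every 7.5 s. Stage B (per
#' segment): motion gate, HR, and RR. Measurements failing the quality
#' rule raise a condition of class `nrr_excluded_measurement`.
#'
#' @param rec an `nrr_recording` (Hb mode; use [od_to_hb()] first for OD).
#' @param p an [nrr_params()] object.
#' @param channel channel id to force; `NULL` selects by SQI.
#' @param sqi_args extra arguments passed to [compute_sqi()].
#' @return data frame of class `nrr_results`, one row per segment:
#'   `method`, `start_s`, `included`, `clean_frac`, `hr_bpm`, `rr_bpm`,
#'   `band_rr_lo`, `band_rr_hi`. HR/RR are `NA` for dismissed segments.
#' @export
run_nrr <- function(rec, p = nrr_params(), channel = NULL,
                    sqi_args = list()) {
  if (rec$mode != "Hb") stop("run_nrr expects an Hb-mode recording")
  if (is.null(channel)) {
    ids <- channel_ids(rec)
    sqis <- lapply(ids, function(ch)
      do.call(compute_sqi, c(list(thb(rec, ch), rec$fs), sqi_args)))
    names(sqis) <- ids
    sel <- select_channel(sqis)
    if (sel$excluded)
      excluded_measurement("measurement excluded for low signal quality",
                           sel$low_frac)
    channel <- sel$channel
  }
  x <- thb(rec, channel)
  band_hr <- estimate_hr_band(x, rec$fs, p)
  iqr <- compute_iqr_series(x, rec$fs, p)
  segs <- segment_measurement(x, iqr, rec$fs, p)

  rows <- lapply(segs, function(sg) {
    gate <- motion_gate(sg$iqr, p)
    row <- data.frame(method = "nrr", start_s = sg$start_s,
                      included = gate$included, clean_frac = gate$clean_frac,
                      hr_bpm = NA_real_, rr_bpm = NA_real_,
                      band_rr_lo = NA_real_, band_rr_hi = NA_real_)
    if (!gate$included) return(row)
    ok <- tryCatch({
      conv <- convert_segment(sg$thb, gate$mask)
      sp <- multitaper_psd(conv, rec$fs, nw = p$nw, k = p$k,
                           nfft_factor = p$nfft_factor)
      hr <- 60 * dominant_frequency(sp, band_hr)
      rr <- compute_rr(conv, hr, rec$fs, p)
      row$hr_bpm <- hr
      row$rr_bpm <- rr$rr_bpm
      row$band_rr_lo <- rr$band_rr$lo
      row$band_rr_hi <- rr$band_rr$hi
      TRUE
    }, error = function(e) FALSE)
    if (!ok) row$included <- FALSE   # degenerate spectrum/band: mark failed
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "params") <- p
  attr(out, "channel") <- channel
  attr(out, "band_hr") <- band_hr
  class(out) <- c("nrr_results", "data.frame")
  out
}
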