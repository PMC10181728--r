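#' Parameters of the comparator extractors
#'
#' The band-pass (BPF) comparator searches a fixed respiratory band
#' (0.15-2 Hz); the baseline-wander (BW) comparator extracts a smoothed
#' baseline first. Both use the same 30-s/7.5-s segment grid as the NRR
#' algorithm so results align row-for-row. The BW extractor is a
#' reconstruction of a method whose defining description is external;
#' its smoothing constant is exposed here.
#'
#' @param bpf_lo,bpf_hi fixed respiratory band, Hz.
#' @param seg_len_s segment length, seconds.
#' @param overlap_frac segment overlap fraction.
#' @param bw_smooth_s moving-average length of the baseline-wander
#'   extraction, seconds (suppresses cardiac content, keeps breathing).
#' @param nw,k,nfft_factor multitaper settings.
#' @param kaiser_atten_db,kaiser_trans_hz Kaiser design targets.
#' @return an object of class `nrr_baseline_params`.
#' @export
baseline_params <- function(bpf_lo = 0.15, bpf_hi = 2.0,
                            seg_len_s = 30, overlap_frac = 0.75,
                            bw_smooth_s = 0.6,
                            nw = 2.5, k = 5, nfft_factor = 8,
                            kaiser_atten_db = 50, kaiser_trans_hz = 0.1) {
  stopifnot(bpf_lo > 0, bpf_lo < bpf_hi, seg_len_s > 0, bw_smooth_s > 0)
  structure(as.list(environment()), class = "nrr_baseline_params")
}

baseline_segments <- function(x, fs, bp) {
  p <- nrr_params(seg_len_s = bp$seg_len_s, overlap_frac = bp$overlap_frac)
  segment_measurement(x, NULL, fs, p)
}

baseline_rr_segment <- function(seg, fs, bp, prefilter) {
  out <- tryCatch({
    y <- prefilter(linear_detrend(seg))
    # Degenerate (constant) segments leave only rounding residue behind.
    if (max(abs(y)) < 1e-10) stop("zero power in band")
    sp <- multitaper_psd(y, fs, nw = bp$nw, k = bp$k,
                         nfft_factor = bp$nfft_factor)
    b <- band(bp$bpf_lo, bp$bpf_hi)
    sel <- sp$freqs >= b$lo & sp$freqs <= b$hi
    if (all(sp$power[sel] <= 0)) stop("zero power in band")
    60 * dominant_frequency(sp, b)
  }, error = function(e) NA_real_)
  out
}

baseline_run <- function(rec, bp, channel, method, prefilter) {
  if (rec$mode != "Hb") stop("comparators expect an Hb-mode recording")
  x <- thb(rec, channel %||% channel_ids(rec)[1])
  segs <- baseline_segments(x, rec$fs, bp)
  rows <- lapply(segs, function(sg) {
    rr <- baseline_rr_segment(sg$thb, rec$fs, bp, prefilter)
    data.frame(method = method, start_s = sg$start_s,
               included = !is.na(rr), clean_frac = NA_real_,
               hr_bpm = NA_real_, rr_bpm = rr,
               band_rr_lo = bp$bpf_lo, band_rr_hi = bp$bpf_hi)
  })
  out <- do.call(rbind, rows)
  attr(out, "params") <- bp
  class(out) <- c("nrr_results", "data.frame")
  out
}

#' Band-pass filtering (BPF) comparator
#'
#' Per 30-s segment: zero-phase Kaiser band-pass of tHb to the fixed
#' 0.15-2 Hz respiratory band, multitaper spectrum, RR = 60 times the
#' dominant in-band frequency. No motion-artifact gating is applied;
#' that is the comparator's documented weakness.
#'
#' @param rec an `nrr_recording` in Hb mode.
#' @param bp a [baseline_params()] object.
#' @param channel channel id; defaults to the first.
#' @return an `nrr_results` data frame with `method = "bpf"`.
#' @export
run_bpf <- function(rec, bp = baseline_params(), channel = NULL) {
  baseline_run(rec, bp, channel, "bpf", function(seg)
    kaiser_bandpass_zerophase(seg, rec$fs, bp$bpf_lo, bp$bpf_hi,
                              atten_db = bp$kaiser_atten_db,
                              trans_hz = bp$kaiser_trans_hz))
}

#' Baseline-wander (BW) comparator, reconstructed
#'
#' Per 30-s segment: the baseline-wander component is estimated by a
#' centred moving average of tHb over `bw_smooth_s` seconds (removing
#' cardiac pulsation while keeping the respiratory modulation), and RR
#' is the dominant spectral frequency of that baseline within the fixed
#' respiratory band. This is a labelled reconstruction - a plausible
#' baseline-wander extractor, not a fidelity claim.
#'
#' @inheritParams run_bpf
#' @return an `nrr_results` data frame with `method = "bw"`.
#' @export
run_bw <- function(rec, bp = baseline_params(), channel = NULL) {
  smooth <- function(seg)   # centred moving average = seg minus its high-pass
    seg - moving_average_highpass(seg, rec$fs, bp$bw_smooth_s)
  out <- baseline_run(rec, bp, channel, "bw", smooth)
  attr(out, "reconstructed") <- TRUE
  out
}
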