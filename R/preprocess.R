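#' Modified Beer-Lambert conversion parameters
#'
#' Extinction coefficients default to commonly tabulated values for
#' hemoglobin at 760 and 850 nm (in 1/(mM*cm)); the differential
#' pathlength factors and the 2.15 cm transmitter-receiver separation
#' match a neonatal forehead probe. All values are overridable, since
#' instruments ship their own calibration tables.
#'
#' @param wavelengths two wavelengths in nm.
#' @param extinction 2x2 matrix, rows = wavelengths, columns =
#'   c(O2Hb, HHb), units 1/(mM*cm).
#' @param dpf differential pathlength factor per wavelength.
#' @param separation transmitter-receiver distance in cm.
#' @return an object of class `nrr_blp`.
#' @export
beer_lambert_params <- function(wavelengths = c(760, 850),
                                extinction = matrix(c(0.586, 1.058,
                                                      1.548, 0.691),
                                                    nrow = 2,
                                                    dimnames = list(NULL, c("O2Hb", "HHb"))),
                                dpf = c(5.1, 4.7),
                                separation = 2.15) {
  if (length(wavelengths) != 2) stop("exactly two wavelengths required")
  if (!all(dim(extinction) == c(2, 2))) stop("extinction must be 2x2")
  if (abs(det(extinction)) < 1e-12) stop("extinction matrix is singular")
  if (any(dpf <= 0)) stop("dpf must be positive")
  if (separation <= 0) stop("separation must be positive")
  structure(list(wavelengths = wavelengths, extinction = extinction,
                 dpf = dpf, separation = separation),
            class = "nrr_blp")
}

# Forward map: OD change per wavelength from concentration changes (uM).
# dOD(lambda) = sep * dpf(lambda) * sum_c eps(lambda, c) * dc_mM
blp_matrix <- function(p) diag(p$dpf * p$separation) %*% p$extinction

#' Convert optical densities to hemoglobin concentration changes
#'
#' Solves the 2x2 modified Beer-Lambert system per channel, yielding
#' O2Hb and HHb concentration changes in micromolar.
#'
#' @param rec an `nrr_recording` in OD mode, two wavelengths per channel.
#' @param p a [beer_lambert_params()] object.
#' @return an `nrr_recording` in Hb mode.
#' @export
od_to_hb <- function(rec, p = beer_lambert_params()) {
  if (rec$mode != "OD") stop("od_to_hb requires a recording in OD mode")
  A <- blp_matrix(p)
  Ainv <- solve(A)
  out <- list()
  for (ch in channel_ids(rec)) {
    labs <- paste0(ch, "_", p$wavelengths, "nm")
    if (!all(labs %in% names(rec$data)))
      stop("channel ", ch, " lacks wavelengths matching params (",
           paste(p$wavelengths, collapse = "/"), " nm)")
    od <- rbind(rec$data[[labs[1]]], rec$data[[labs[2]]])
    hb <- 1000 * (Ainv %*% od)   # mM -> uM
    out[[paste0(ch, "_O2Hb")]] <- as.numeric(hb[1, ])
    out[[paste0(ch, "_HHb")]] <- as.numeric(hb[2, ])
  }
  recording(fs = rec$fs, data = out, mode = "Hb", t0 = rec$t0)
}

#' Render hemoglobin concentration changes as optical densities
#'
#' Inverse of [od_to_hb()]; used by the simulator to emit OD-space
#' fixtures that exercise the conversion.
#'
#' @param rec an `nrr_recording` in Hb mode.
#' @param p a [beer_lambert_params()] object.
#' @return an `nrr_recording` in OD mode.
#' @export
hb_to_od <- function(rec, p = beer_lambert_params()) {
  if (rec$mode != "Hb") stop("hb_to_od requires a recording in Hb mode")
  A <- blp_matrix(p)
  out <- list()
  for (ch in channel_ids(rec)) {
    hb <- rbind(rec$data[[paste0(ch, "_O2Hb")]],
                rec$data[[paste0(ch, "_HHb")]]) / 1000  # uM -> mM
    od <- A %*% hb
    out[[paste0(ch, "_", p$wavelengths[1], "nm")]] <- as.numeric(od[1, ])
    out[[paste0(ch, "_", p$wavelengths[2], "nm")]] <- as.numeric(od[2, ])
  }
  recording(fs = rec$fs, data = out, mode = "OD", t0 = rec$t0)
}

#' Signal quality index (proxy) of a tHb series
#'
#' Scores each 10-s window (5-s hop) on an ordinal 1-4 scale from the
#' ratio of spectral power inside the predefined cardiac band
#' (1.25-3.5 Hz) to the total power above 0.5 Hz: strong heartbeat
#' content means good optical coupling. Level 1 is lowest quality;
#' level 2 is the low-quality boundary used by the exclusion rule.
#' The bucket thresholds are configurable so a different quality
#' scorer can be substituted.
#'
#' @param x tHb series (micromolar).
#' @param fs sampling rate, Hz.
#' @param win_s,hop_s window length and hop, seconds.
#' @param cardiac_band an `nrr_band`; the cardiac search band.
#' @param ratio_breaks three increasing cut points mapping the power
#'   ratio to levels 1-4.
#' @param total_above_hz lower limit of the total-power denominator, Hz.
#' @return data frame with columns `window_start_s`, `level`, `ratio`.
#' @export
compute_sqi <- function(x, fs, win_s = 10, hop_s = 5,
                        cardiac_band = band(1.25, 3.5),
                        ratio_breaks = c(0.15, 0.35, 0.6),
                        total_above_hz = 0.5) {
  n <- length(x)
  if (n < win_s * fs) stop("need at least ", win_s, " s of signal")
  starts <- seq(0, n / fs - win_s, by = hop_s)
  L <- round(win_s * fs)
  ratio <- vapply(starts, function(s0) {
    seg <- x[(round(s0 * fs) + 1):(round(s0 * fs) + L)]
    seg <- seg - mean(seg)
    sp <- multitaper_psd(seg, fs, nfft_factor = 2)
    inb <- sp$freqs >= cardiac_band$lo & sp$freqs <= cardiac_band$hi
    tot <- sp$freqs >= total_above_hz
    den <- sum(sp$power[tot])
    if (den <= 0) 0 else sum(sp$power[inb & tot]) / den
  }, 0)
  level <- findInterval(ratio, ratio_breaks) + 1L
  data.frame(window_start_s = starts, level = level, ratio = ratio)
}

#' Select the better NIRS channel and apply the exclusion rule
#'
#' Picks the channel with the greater time-averaged SQI level (ties go
#' to the lowest channel index). The measurement is flagged excluded
#' when strictly more than `exclude_frac` of the selected channel's SQI
#' windows are below level `low_level` (low quality).
#'
#' @param sqis named list of per-channel data frames from [compute_sqi()].
#' @param exclude_frac exclusion fraction (default 0.75, strict).
#' @param low_level the low-quality level boundary (default 2).
#' @return list with `channel` (name), `excluded` (flag), `mean_levels`,
#'   `low_frac` (fraction of low-quality windows on the selected channel).
#' @export
select_channel <- function(sqis, exclude_frac = 0.75, low_level = 2) {
  if (length(sqis) == 0) stop("no SQI series supplied")
  if (any(vapply(sqis, nrow, 0L) == 0)) stop("empty SQI series")
  mean_levels <- vapply(sqis, function(d) mean(d$level), 0)
  pick <- which.max(mean_levels)          # ties -> lowest index
  low_frac <- mean(sqis[[pick]]$level < low_level)
  list(channel = names(sqis)[pick] %||% pick,
       excluded = low_frac > exclude_frac,
       mean_levels = mean_levels, low_frac = low_frac)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
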