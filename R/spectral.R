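#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` Slepian sequences of length `n` with
#' time-bandwidth product `nw`, as unit-energy columns. These are the
#' eigenvectors of the classic symmetric tridiagonal operator, found by
#' Sturm-count bisection and inverse iteration, so the cost is O(n) per
#' taper and long recordings are cheap. Results are cached per session.
#'
#' @param n taper length in samples.
#' @param nw standardized half bandwidth (time-bandwidth product).
#' @param k number of tapers.
#' @return numeric `n x k` matrix; each column has unit energy.
#' @export
dpss_tapers <- function(n, nw = 2.5, k = 5) {
  key <- paste(n, nw, k, sep = "|")
  hit <- .taper_cache[[key]]
  if (!is.null(hit)) return(hit)
  v <- .dpss_tapers(as.integer(n), as.numeric(nw), as.integer(k))
  .taper_cache[[key]] <- v
  v
}

#' Frequency band
#'
#' @param lo,hi band edges in Hz, `0 <= lo < hi`.
#' @return an object of class `nrr_band`.
#' @export
band <- function(lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || lo < 0 || lo >= hi)
    stop("invalid band: need 0 <= lo < hi, got [", lo, ", ", hi, "]")
  structure(list(lo = lo, hi = hi), class = "nrr_band")
}

#' @export
print.nrr_band <- function(x, ...) {
  cat(sprintf("<band [%.4g, %.4g] Hz>\n", x$lo, x$hi))
  invisible(x)
}

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Multitaper power spectral density
#'
#' Average of `k` eigenspectra under Slepian tapers (NW = 2.5, K = 5 by
#' default), evaluated on an `nfft`-point zero-padded grid and returned
#' one-sided. Power is scaled as a density (units^2/Hz) so that the
#' integral over frequency approximates the tapered-signal variance.
#'
#' @param x numeric series, uniformly sampled.
#' @param fs sampling rate in Hz.
#' @param nfft FFT length; defaults to the next power of two at least
#'   `nfft_factor` times `length(x)`.
#' @param nw,k taper parameters.
#' @param nfft_factor zero-padding factor used when `nfft` is missing.
#' @return an object of class `nrr_spectrum` with fields `freqs`, `power`,
#'   `nw`, `k`, `fs`, `nfft`.
#' @export
multitaper_psd <- function(x, fs, nfft = NULL, nw = 2.5, k = 5,
                           nfft_factor = 8) {
  n <- length(x)
  if (n < k + 1) stop("signal shorter than taper count: length ", n)
  if (is.null(nfft)) nfft <- next_pow2(nfft_factor * n)
  nfft <- as.integer(nfft)
  if (nfft < n) stop("nfft must be at least the signal length")
  tap <- dpss_tapers(n, nw, k)
  tx <- tap * x                      # column-wise taper * signal
  if (nfft > n) tx <- rbind(tx, matrix(0, nfft - n, k))
  eig <- Mod(mvfft(tx))^2 / fs       # two-sided eigenspectra
  half <- nfft %/% 2L + 1L
  pw <- rowMeans(eig)[seq_len(half)]
  if (half > 2L) pw[2:(half - 1L)] <- 2 * pw[2:(half - 1L)]
  structure(list(freqs = (seq_len(half) - 1) * fs / nfft,
                 power = pw, nw = nw, k = k, fs = fs, nfft = nfft),
            class = "nrr_spectrum")
}

#' Dominant frequency within a band
#'
#' Frequency of the maximum power among grid points with
#' `b$lo <= f <= b$hi`; ties resolve to the lowest frequency.
#'
#' @param s an `nrr_spectrum`.
#' @param b an `nrr_band`.
#' @return frequency in Hz.
#' @export
dominant_frequency <- function(s, b) {
  sel <- which(s$freqs >= b$lo & s$freqs <= b$hi)
  if (length(sel) == 0L)
    stop("no spectrum grid points inside band [", b$lo, ", ", b$hi, "] Hz")
  s$freqs[sel[which.max(s$power[sel])]]
}

# Kaiser window beta for a target stop-band attenuation (dB).
kaiser_beta <- function(atten_db) {
  if (atten_db > 50) 0.1102 * (atten_db - 8.7)
  else if (atten_db >= 21) 0.5842 * (atten_db - 21)^0.4 + 0.07886 * (atten_db - 21)
  else 0
}

#' Zero-phase FIR Kaiser band-pass filter
#'
#' Designs a linear-phase FIR band-pass with a Kaiser window targeting
#' `atten_db` stop-band attenuation and a transition width of `trans_hz`,
#' and applies it with zero net phase (two centred passes of the symmetric
#' filter, with reflection padding of three times the filter order). When
#' the target transition width would require a filter longer than a third
#' of the signal, the order is capped at `floor((length(x) - 1)/3)` and
#' the transition band widens accordingly.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param lo,hi pass-band edges, Hz, `0 < lo < hi < fs/2`.
#' @param atten_db stop-band attenuation target in dB.
#' @param trans_hz transition width target in Hz.
#' @return filtered series, same length as `x`.
#' @export
kaiser_bandpass_zerophase <- function(x, fs, lo, hi,
                                      atten_db = 50, trans_hz = 0.1) {
  n <- length(x)
  if (!(lo > 0 && lo < hi && hi < fs / 2))
    stop("invalid pass band: need 0 < lo < hi < fs/2, got [", lo, ", ", hi, "]")
  if (hi - lo <= trans_hz)
    stop("band too narrow for the designed transition width (", trans_hz, " Hz)")
  beta <- kaiser_beta(atten_db)
  dw <- 2 * pi * trans_hz / fs
  ord <- ceiling((atten_db - 7.95) / (2.285 * dw))
  ord_max <- (n - 1) %/% 3
  ord <- min(ord, ord_max)
  if (ord %% 2 == 1) ord <- ord - 1       # Type I (odd tap count)
  if (ord < 8) stop("signal too short for the band-pass filter")
  key <- paste("fir", ord, beta, lo, hi, fs, sep = "|")
  h <- .taper_cache[[key]]
  if (is.null(h)) {
    h <- signal::fir1(ord, c(lo, hi) / (fs / 2), type = "pass",
                      window = signal::kaiser(ord + 1, beta))
    .taper_cache[[key]] <- h
  }
  pad <- min(3 * ord, n - 1)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  # Forward-backward application of the symmetric FIR equals convolution
  # with its autocorrelation, i.e. multiplication by |H(w)|^2 -- applied
  # here in the frequency domain with enough zero padding that the
  # circular wrap-around stays inside the discarded reflection pad.
  np <- length(xp)
  L <- next_pow2(np + 2 * ord + 2)
  X <- fft(c(xp, numeric(L - np)))
  H <- fft(c(h, numeric(L - ord - 1)))
  # |H|^2 is real, i.e. a zero-phase (zero-delay) composite kernel.
  y <- Re(fft(X * (Mod(H)^2), inverse = TRUE)) / L
  y[(pad + 1):(pad + n)]
}

#' Moving-average high-pass filter
#'
#' Subtracts a centred moving average of length `round(win_s * fs)` from
#' the signal; edge windows shrink to the available samples.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param win_s window length in seconds.
#' @return high-passed series, same length as `x`.
#' @export
moving_average_highpass <- function(x, fs, win_s = 1) {
  n <- length(x)
  L <- round(win_s * fs)
  if (L < 1) stop("window shorter than one sample")
  hl <- (L - 1) %/% 2
  hr <- L - 1 - hl
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  a <- pmax(i - hl, 1L)
  b <- pmin(i + hr, n)
  x - (cs[b + 1] - cs[a]) / (b - a + 1)
}
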