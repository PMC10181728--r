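#' Synthetic neonatal-NIRS scenario configuration
#'
#' Describes a two-channel recording whose tHb is the sum of a cardiac
#' sinusoid (instantaneous frequency HR/60), a respiratory sinusoid
#' (RR/60), a narrowband Mayer-wave component, slow drift, white noise,
#' and sparse high-amplitude motion-artifact bursts, on top of a constant
#' tHb operating point. Trajectories may be a constant (BPM), a function
#' of time, or a two-column breakpoint matrix `(time_s, bpm)` interpolated
#' linearly.
#'
#' @param duration_s recording length, seconds (>= 60).
#' @param fs_signal NIRS sampling rate, Hz.
#' @param fs_ref reference RR sampling rate, Hz.
#' @param hr_bpm heart-rate trajectory, BPM, inside (75, 210).
#' @param rr_bpm respiratory-rate trajectory, BPM, strictly below HR.
#' @param cardiac_amp,resp_amp,mayer_amp,drift_amp component amplitudes
#'   in tHb, micromolar.
#' @param mayer_freq Mayer-wave centre frequency, Hz.
#' @param noise_sd white-noise standard deviation on tHb, micromolar.
#' @param artifact_rate expected motion-artifact bursts per minute.
#' @param artifact_amp burst amplitude, micromolar (much larger than
#'   `cardiac_amp`).
#' @param artifact_duration_s burst duration, seconds.
#' @param baseline_uM tHb operating point, micromolar; gives the
#'   median-normalized IQR statistic a physiological scale.
#' @param channel_scales per-channel gain on the physiological content;
#'   the second channel is degraded by default so channel selection has
#'   something to do.
#' @param seed integer seed; identical seeds give identical recordings.
#' @return an object of class `nrr_simconfig`.
#' @export
sim_config <- function(duration_s = 600, fs_signal = 100, fs_ref = 0.5,
                       hr_bpm = 140, rr_bpm = 45,
                       cardiac_amp = 0.25, resp_amp = 0.15,
                       mayer_amp = 0.08, mayer_freq = 0.08,
                       drift_amp = 0.5, noise_sd = 0.05,
                       artifact_rate = 0, artifact_amp = 5,
                       artifact_duration_s = 2,
                       baseline_uM = 60,
                       channel_scales = c(1, 0.5),
                       seed = 1L) {
  cfg <- structure(list(duration_s = duration_s, fs_signal = fs_signal,
                        fs_ref = fs_ref, hr_bpm = hr_bpm, rr_bpm = rr_bpm,
                        cardiac_amp = cardiac_amp, resp_amp = resp_amp,
                        mayer_amp = mayer_amp, mayer_freq = mayer_freq,
                        drift_amp = drift_amp, noise_sd = noise_sd,
                        artifact_rate = artifact_rate,
                        artifact_amp = artifact_amp,
                        artifact_duration_s = artifact_duration_s,
                        baseline_uM = baseline_uM,
                        channel_scales = channel_scales,
                        seed = as.integer(seed)),
                   class = "nrr_simconfig")
  validate_sim_config(cfg)
  cfg
}

trajectory_fun <- function(tr, field) {
  if (is.function(tr)) return(tr)
  if (is.numeric(tr) && length(tr) == 1) return(function(t) rep(tr, length(t)))
  if (is.matrix(tr) && ncol(tr) == 2)
    return(function(t) approx(tr[, 1], tr[, 2], xout = t, rule = 2)$y)
  stop("field ", field, ": trajectory must be a constant, function, or ",
       "two-column (time_s, bpm) matrix")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, msg) stop("sim_config field ", field, ": ", msg)
  if (cfg$duration_s < 60) bad("duration_s", "must be at least 60 s")
  if (cfg$fs_signal <= 0) bad("fs_signal", "must be positive")
  tt <- seq(0, cfg$duration_s, by = 0.5)
  hr <- trajectory_fun(cfg$hr_bpm, "hr_bpm")(tt)
  rr <- trajectory_fun(cfg$rr_bpm, "rr_bpm")(tt)
  if (any(hr <= 75 | hr >= 210))
    bad("hr_bpm", "trajectory must stay inside (75, 210) BPM")
  if (any(hr <= rr))
    bad("rr_bpm", "trajectory must stay strictly below the HR trajectory")
  if (cfg$fs_signal <= 2 * max(hr) / 60)
    bad("fs_signal", "must exceed twice the maximum cardiac frequency")
  amps <- c(cardiac_amp = cfg$cardiac_amp, resp_amp = cfg$resp_amp,
            mayer_amp = cfg$mayer_amp, drift_amp = cfg$drift_amp,
            noise_sd = cfg$noise_sd, artifact_amp = cfg$artifact_amp,
            artifact_rate = cfg$artifact_rate,
            baseline_uM = cfg$baseline_uM)
  neg <- names(amps)[amps < 0]
  if (length(neg)) bad(neg[1], "must be non-negative")
  invisible(cfg)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate a neonatal NIRS measurement with known ground truth
#'
#' Generates a two-channel Hb-mode recording whose channel-1 tHb is the
#' configured physiological mixture, plus a 0.5 Hz ground-truth HR/RR
#' series and the list of injected artifact intervals. Phase is
#' integrated from the instantaneous frequency, so trajectories may vary
#' smoothly. Identical seeds give identical output.
#'
#' @param cfg an [sim_config()] object.
#' @return list with elements `recording` (`nrr_recording`, Hb mode),
#'   `truth` (list: `hr_series`, `rr_series`, `artifact_intervals`),
#'   `reference` (`nrr_reference` built from the RR ground truth), and
#'   `cfg`.
#' @export
simulate_measurement <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, {
    fs <- cfg$fs_signal
    n <- round(cfg$duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    hr_f <- trajectory_fun(cfg$hr_bpm, "hr_bpm")
    rr_f <- trajectory_fun(cfg$rr_bpm, "rr_bpm")

    phase <- function(freq_hz) 2 * pi * cumsum(freq_hz) / fs
    cardiac <- cfg$cardiac_amp * sin(phase(hr_f(t) / 60))
    resp <- cfg$resp_amp * sin(phase(rr_f(t) / 60))

    # Narrowband Mayer activity: centre-frequency sinusoid with a slow
    # random phase walk spreading power over a few hundredths of a Hz.
    mayer <- if (cfg$mayer_amp > 0)
      cfg$mayer_amp * sin(2 * pi * cfg$mayer_freq * t +
                            cumsum(rnorm(n, 0, 0.3 / sqrt(fs))))
    else numeric(n)

    # Slow drift: three sub-0.02 Hz sinusoids with random phases.
    drift <- if (cfg$drift_amp > 0) {
      f <- c(0.004, 0.009, 0.017)
      ph <- runif(3, 0, 2 * pi)
      cfg$drift_amp * (sin(2 * pi * f[1] * t + ph[1]) +
                         0.6 * sin(2 * pi * f[2] * t + ph[2]) +
                         0.3 * sin(2 * pi * f[3] * t + ph[3])) / 1.9
    } else numeric(n)

    # Motion artifacts: Poisson-count bursts of boxcar-windowed random
    # steps (level redrawn every 0.1 s), amplitude >> cardiac_amp.
    artifact <- numeric(n)
    intervals <- matrix(numeric(0), ncol = 2,
                        dimnames = list(NULL, c("start_s", "end_s")))
    if (cfg$artifact_rate > 0) {
      n_ev <- rpois(1, cfg$artifact_rate * cfg$duration_s / 60)
      if (n_ev > 0) {
        starts <- sort(runif(n_ev, 0, cfg$duration_s - cfg$artifact_duration_s))
        ends <- pmin(starts + cfg$artifact_duration_s, cfg$duration_s)
        intervals <- cbind(start_s = starts, end_s = ends)
        step <- max(1L, round(0.1 * fs))
        for (i in seq_len(n_ev)) {
          idx <- (floor(starts[i] * fs) + 1):min(n, ceiling(ends[i] * fs))
          levels <- rep(runif(ceiling(length(idx) / step), -1, 1),
                        each = step)[seq_along(idx)]
          artifact[idx] <- artifact[idx] + cfg$artifact_amp * levels
        }
      }
    }

    physio <- cardiac + resp + mayer + drift
    data <- list()
    for (ci in seq_along(cfg$channel_scales)) {
      ch_thb <- cfg$baseline_uM + cfg$channel_scales[ci] * physio + artifact
      # Equal O2Hb/HHb split of every component; independent noise per
      # chromophore such that the tHb noise sd equals noise_sd.
      o2 <- ch_thb / 2 + rnorm(n, 0, cfg$noise_sd / sqrt(2))
      hh <- ch_thb / 2 + rnorm(n, 0, cfg$noise_sd / sqrt(2))
      data[[paste0("ch", ci, "_O2Hb")]] <- o2
      data[[paste0("ch", ci, "_HHb")]] <- hh
    }

    n_ref <- floor(cfg$duration_s * cfg$fs_ref)
    t_ref <- (seq_len(n_ref) - 1) / cfg$fs_ref
    truth <- list(hr_series = hr_f(t_ref), rr_series = rr_f(t_ref),
                  artifact_intervals = intervals)
    list(recording = recording(fs, data, mode = "Hb"),
         truth = truth,
         reference = reference_rr(truth$rr_series, fs_ref = cfg$fs_ref),
         cfg = cfg)
  })
}

#' Write a simulated measurement as on-disk fixture files
#'
#' Emits `signal.csv` (the recording), `reference.csv` (0.5 Hz RR ground
#' truth), and `config.json` (scenario echo) into `dir`; all three
#' round-trip losslessly through the readers.
#'
#' @param sim output of [simulate_measurement()].
#' @param dir writable directory.
#' @param od render the recording in OD space via the inverse
#'   Beer-Lambert map before writing.
#' @param blp Beer-Lambert parameters used when `od = TRUE`.
#' @return named character vector of the written paths.
#' @export
write_fixture <- function(sim, dir, od = FALSE, blp = beer_lambert_params()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec <- if (od) hb_to_od(sim$recording, blp) else sim$recording
  paths <- c(signal = file.path(dir, "signal.csv"),
             reference = file.path(dir, "reference.csv"),
             config = file.path(dir, "config.json"))
  write_recording(rec, paths["signal"])
  write_reference(sim$reference, paths["reference"])
  cfg <- sim$cfg
  cfg_out <- lapply(unclass(cfg), function(v)
    if (is.function(v)) "<function>" else if (is.matrix(v)) as.data.frame(v) else v)
  write_config(cfg_out, paths["config"])
  paths
}
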