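#' NIRS recording container
#'
#' A uniform-rate multichannel recording. `data` holds one numeric series
#' per labelled channel; labels are `<channel>_<wavelength>nm` in OD mode
#' (e.g. `ch1_760nm`) or `<channel>_<chromophore>` in Hb mode
#' (e.g. `ch1_O2Hb`, `ch1_HHb`, concentration changes in micromolar).
#'
#' @param fs sampling rate, Hz.
#' @param data named list of equal-length numeric series.
#' @param mode `"OD"` or `"Hb"`.
#' @param t0 time of the first sample, seconds.
#' @return an object of class `nrr_recording`.
#' @export
recording <- function(fs, data, mode = c("Hb", "OD"), t0 = 0) {
  mode <- match.arg(mode)
  if (!is.list(data) || is.null(names(data)) || anyDuplicated(names(data)))
    stop("data must be a named list with unique labels")
  len <- unique(vapply(data, length, 0L))
  if (length(len) != 1L) stop("all channel series must have equal length")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  structure(list(fs = fs, t0 = t0, mode = mode, data = data),
            class = "nrr_recording")
}

#' @export
print.nrr_recording <- function(x, ...) {
  cat(sprintf("<nrr_recording: %s mode, %d series x %d samples @ %g Hz (%.1f s)>\n",
              x$mode, length(x$data), length(x$data[[1]]), x$fs,
              length(x$data[[1]]) / x$fs))
  cat(" labels:", paste(names(x$data), collapse = ", "), "\n")
  invisible(x)
}

#' Sample times of a recording
#' @param rec an `nrr_recording`.
#' @return numeric vector of times in seconds.
#' @export
rec_times <- function(rec) rec$t0 + (seq_along(rec$data[[1]]) - 1) / rec$fs

#' Channel identifiers of a recording
#' @param rec an `nrr_recording`.
#' @return character vector of channel ids (label prefixes).
#' @export
channel_ids <- function(rec) unique(sub("_[^_]+$", "", names(rec$data)))

#' Total hemoglobin series of one channel
#'
#' @param rec an `nrr_recording` in Hb mode.
#' @param channel channel id, e.g. `"ch1"`; defaults to the first.
#' @return numeric tHb = O2Hb + HHb series (micromolar).
#' @export
thb <- function(rec, channel = channel_ids(rec)[1]) {
  if (rec$mode != "Hb") stop("tHb requires a recording in Hb mode")
  o <- rec$data[[paste0(channel, "_O2Hb")]]
  h <- rec$data[[paste0(channel, "_HHb")]]
  if (is.null(o) || is.null(h)) stop("channel not found: ", channel)
  o + h
}

#' Reference respiratory-rate series
#'
#' @param rr numeric RR series in breaths per minute; `NA` marks gaps.
#' @param fs_ref sampling rate, Hz (0.5 for the bedside monitor).
#' @param t0 time of the first sample, seconds.
#' @return an object of class `nrr_reference`.
#' @export
reference_rr <- function(rr, fs_ref = 0.5, t0 = 0) {
  if (any(rr[!is.na(rr)] <= 0)) stop("reference RR must be positive where present")
  structure(list(fs_ref = fs_ref, t0 = t0, rr = as.numeric(rr)),
            class = "nrr_reference")
}

#' @export
print.nrr_reference <- function(x, ...) {
  cat(sprintf("<nrr_reference: %d samples @ %g Hz, %d gaps>\n",
              length(x$rr), x$fs_ref, sum(is.na(x$rr))))
  invisible(x)
}

#' Sample times of a reference series
#' @param ref an `nrr_reference`.
#' @return numeric vector of times in seconds.
#' @export
ref_times <- function(ref) ref$t0 + (seq_along(ref$rr) - 1) / ref$fs_ref

infer_mode <- function(labels) {
  if (all(grepl("_[0-9.]+nm$", labels))) "OD"
  else if (all(grepl("_(O2Hb|HHb)$", labels))) "Hb"
  else stop("cannot infer mode from labels: ", paste(labels, collapse = ", "))
}

check_uniform <- function(t, tol = 1e-6) {
  if (length(t) < 2) stop("need at least two samples")
  dt <- diff(t)
  bad <- which(abs(dt - dt[1]) > tol)
  if (length(bad))
    stop("non-uniform time base near row ", bad[1] + 1,
         " (dt = ", signif(dt[bad[1]], 8), " vs ", signif(dt[1], 8), ")")
  dt[1]
}

#' Read a recording from delimited text
#'
#' Expects a header row `time_s,<label>,...`; comment lines start with `#`.
#' The time base must be uniform to within 1e-6 s.
#'
#' @param path file path.
#' @return an `nrr_recording`.
#' @export
read_recording <- function(path) {
  hdr <- scan(path, what = character(), sep = ",", nlines = 1,
              comment.char = "#", quiet = TRUE)
  if (anyDuplicated(hdr)) stop("duplicate column labels in ", path)
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  if (names(df)[1] != "time_s") stop("first column must be time_s")
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))
      stop("unparseable rows in ", path, " (column ", names(df)[j],
           ", first near line ", (if (length(bad)) bad[1] else 1L) + 1L, ")")
    }
  }
  if (anyNA(df)) stop("unparseable rows in ", path, " (first near line ",
                      which(rowSums(is.na(df)) > 0)[1] + 1L, ")")
  dt <- check_uniform(df$time_s)
  labels <- names(df)[-1]
  recording(fs = 1 / dt, data = as.list(df[-1]),
            mode = infer_mode(labels), t0 = df$time_s[1])
}

#' Write a recording to delimited text
#' @param rec an `nrr_recording`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  unit <- if (rec$mode == "Hb") "micromolar concentration change" else "optical density"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# NIRS recording, fs = %g Hz, mode = %s, units = %s",
                       rec$fs, rec$mode, unit)), con)
  df <- data.frame(time_s = rec_times(rec), rec$data, check.names = FALSE)
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference respiratory-rate file
#'
#' Expects columns `time_s,rr_bpm`; empty/NA values mark gaps.
#'
#' @param path file path.
#' @return an `nrr_reference`.
#' @export
read_reference <- function(path) {
  df <- read.csv(path, comment.char = "#")
  if (!identical(names(df), c("time_s", "rr_bpm")))
    stop("reference file must have columns time_s,rr_bpm")
  dt <- check_uniform(df$time_s)
  reference_rr(df$rr_bpm, fs_ref = 1 / dt, t0 = df$time_s[1])
}

#' Write a reference respiratory-rate file
#' @param ref an `nrr_reference`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  df <- data.frame(time_s = ref_times(ref), rr_bpm = ref$rr)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write per-segment extraction results
#'
#' One row per segment: `method,start_s,included,clean_frac,hr_bpm,rr_bpm`.
#' Excluded segments carry explicit `NA` markers for HR/RR.
#'
#' @param results a results data frame from [run_nrr()], [run_bpf()] or
#'   [run_bw()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  write.csv(results, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read per-segment extraction results
#' @param path file path.
#' @return a results data frame.
#' @export
read_results <- function(path) {
  df <- read.csv(path, comment.char = "#")
  need <- c("method", "start_s", "included", "clean_frac", "hr_bpm", "rr_bpm")
  if (!all(need %in% names(df)))
    stop("results file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' Read / write a JSON configuration
#' @param path file path.
#' @return named list of configuration values.
#' @export
read_config <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' @rdname read_config
#' @param cfg named list to serialize.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
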