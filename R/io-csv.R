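#' Read a recording from disk
#'
#' Reads either standard EDF (16-bit European Data Format, one signal)
#' or columnar CSV. A CSV file may have two columns (`time_s`,
#' `amplitude_uv`), in which case the sampling rate is inferred from the
#' time grid (which must be uniform within 1 ppm), or a single
#' `amplitude_uv` column together with a declared `sampling_rate_hz`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"edf"` or `"csv"`.
#' @param sampling_rate_hz Declared rate for single-column CSV.
#' @param subject Optional [subject_info()] attached to the result.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"),
                           sampling_rate_hz = NULL, subject = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") return(read_recording_edf(path, subject = subject))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("time_s", "amplitude_uv") %in% names(df))) {
    dt <- diff(df$time_s)
    if (length(dt) == 0L) abort("need at least two samples to infer rate.")
    if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * mean(dt)) {
      abort("time grid is not uniform within 1 ppm; cannot infer rate.")
    }
    rate <- 1 / mean(dt)
    check_finite_column(df$amplitude_uv)
    eeg_recording(df$amplitude_uv, rate, subject = subject,
                  start_offset_s = df$time_s[[1L]])
  } else if ("amplitude_uv" %in% names(df) || ncol(df) == 1L) {
    if (is.null(sampling_rate_hz)) {
      abort("single-column CSV requires a declared `sampling_rate_hz`.")
    }
    amp <- if ("amplitude_uv" %in% names(df)) df$amplitude_uv else df[[1L]]
    check_finite_column(amp)
    eeg_recording(amp, sampling_rate_hz, subject = subject)
  } else {
    abort("CSV must have (time_s, amplitude_uv) or one amplitude column.")
  }
}

check_finite_column <- function(x) {
  bad <- which(!is.finite(x))
  if (length(bad) > 0L) {
    abort(sprintf("non-finite amplitude at row %d.", bad[[1L]]))
  }
  invisible(x)
}

#' Write a recording to disk
#'
#' @param rec An [eeg_recording()].
#' @param path Output path; extension `.edf` selects EDF, anything else
#'   CSV (`time_s`, `amplitude_uv`).
#' @param format `"auto"`, `"edf"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "csv")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") return(write_recording_edf(rec, path))
  n <- length(rec$samples)
  readr::write_csv(
    tibble(time_s = rec$start_offset_s + (seq_len(n) - 1L) / rec$sampling_rate_hz,
           amplitude_uv = rec$samples),
    path, progress = FALSE
  )
  invisible(path)
}

event_columns <- c("start_s", "end_s", "label", "duration_s",
                   "dominant_freq_hz", "harmonic_ratio", "mean_band_power")

#' Write an event table to CSV
#'
#' Events must be sorted and non-overlapping. Metric columns that are
#' absent or `NA` are written as empty fields, so plain intervals and
#' fully characterized SWD events share one schema.
#'
#' @param events Event tibble (see [event_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  events <- as_tibble(events)
  if (nrow(events) > 0L) {
    if (is.unsorted(events$start_s)) abort("events must be sorted by start_s.")
    ov <- first_overlap(events)
    if (!is.null(ov)) {
      abort(sprintf("events %d and %d overlap; refusing to write.",
                    ov[[1L]], ov[[2L]]))
    }
  }
  out <- tibble(start_s = as.numeric(events$start_s %||% numeric()),
                end_s = as.numeric(events$end_s %||% numeric()))
  out$label <- if ("label" %in% names(events)) events$label else "swd"
  out$duration_s <- out$end_s - out$start_s
  for (col in c("dominant_freq_hz", "harmonic_ratio", "mean_band_power")) {
    out[[col]] <- if (col %in% names(events)) as.numeric(events[[col]]) else
      rep(NA_real_, nrow(out))
  }
  if (nrow(out) == 0L) out <- out[0, event_columns]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read an event table from CSV
#'
#' @param path Path written by [write_events()] (or any CSV with at
#'   least `start_s` and `end_s` columns).
#' @return An event tibble.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(label = readr::col_character(),
                                                .default = readr::col_double()))
  if (!all(c("start_s", "end_s") %in% names(df))) {
    abort("event CSV must contain start_s and end_s columns.")
  }
  if (!"label" %in% names(df)) df$label <- "swd"
  df$label[is.na(df$label)] <- "swd"
  df$duration_s <- df$end_s - df$start_s
  for (col in setdiff(event_columns, names(df))) df[[col]] <- NA_real_
  dplyr::arrange(as_tibble(df[event_columns]), .data$start_s)
}

#' Construct a stimulus log
#'
#' Onset times of acoustic stimuli (buzzer tones) delivered during a
#' session, with the tone parameters used in the interruption
#' experiment (2 kHz dominant frequency at 82 dB by default).
#'
#' @param onsets_s Strictly increasing onset times (seconds).
#' @param tone_freq_hz Dominant tone frequency (Hz).
#' @param level_db Sound level at the cage center (dB).
#' @return An object of class `stimulus_log`.
#' @export
stimulus_log <- function(onsets_s = numeric(), tone_freq_hz = 2000,
                         level_db = 82) {
  onsets_s <- as.numeric(onsets_s)
  if (anyDuplicated(onsets_s)) {
    abort("duplicate stimulus onsets are not allowed.")
  }
  if (is.unsorted(onsets_s, strictly = TRUE)) {
    warn("stimulus onsets were not sorted; sorting.")
    onsets_s <- sort(onsets_s)
  }
  structure(list(onsets_s = onsets_s, tone_freq_hz = tone_freq_hz,
                 level_db = level_db),
            class = "stimulus_log")
}

#' @export
print.stimulus_log <- function(x, ...) {
  cat(sprintf("<stimulus_log: %d onsets, %g Hz tone at %g dB>\n",
              length(x$onsets_s), x$tone_freq_hz, x$level_db))
  invisible(x)
}

#' Read a stimulus log from CSV
#'
#' @param path CSV with an `onset_s` column (a header-only or empty file
#'   yields an empty log). Unsorted onsets are sorted with a warning;
#'   duplicated onsets are an error.
#' @param ... Passed to [stimulus_log()] (tone parameters).
#' @return A [stimulus_log()].
#' @export
read_stimulus_log <- function(path, ...) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0L) return(stimulus_log(numeric(), ...))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0L) return(stimulus_log(numeric(), ...))
  if (!"onset_s" %in% names(df)) abort("stimulus CSV needs an onset_s column.")
  stimulus_log(df$onset_s, ...)
}

#' Write a stimulus log to CSV
#' @param stim A [stimulus_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stimulus_log <- function(stim, path) {
  stopifnot(inherits(stim, "stimulus_log"))
  readr::write_csv(tibble(onset_s = stim$onsets_s), path, progress = FALSE)
  invisible(path)
}
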