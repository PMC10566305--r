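#' Describe a recorded animal
#'
#' Subject metadata attached to a recording. Genotype and treatment are
#' closed vocabularies; genotype is rendered in the conventional allele
#' notation (`"-/-"`, `"+/-"`, `"+/+"`) by [format()].
#'
#' @param id Subject identifier (string).
#' @param genotype One of `"hom_ko"`, `"het"`, `"wt"`.
#' @param age_months Age in months (> 0).
#' @param treatment One of `"none"`, `"vpa"`.
#' @param sex One of `"m"`, `"f"`, `"unknown"`.
#' @return An object of class `swd_subject`.
#' @examples
#' subject_info("r01", "hom_ko", age_months = 8)
#' @export
subject_info <- function(id, genotype = c("wt", "het", "hom_ko"),
                         age_months = 6,
                         treatment = c("none", "vpa"),
                         sex = c("unknown", "m", "f")) {
  genotype <- match.arg(genotype)
  treatment <- match.arg(treatment)
  sex <- match.arg(sex)
  if (!is.numeric(age_months) || length(age_months) != 1L || age_months <= 0) {
    abort("`age_months` must be a single positive number.")
  }
  structure(
    list(id = as.character(id), genotype = genotype,
         age_months = as.numeric(age_months), treatment = treatment,
         sex = sex),
    class = "swd_subject"
  )
}

#' @export
format.swd_subject <- function(x, ...) {
  alleles <- c(hom_ko = "-/-", het = "+/-", wt = "+/+")[[x$genotype]]
  sprintf("<subject %s (%s), %.3g mo, %s%s>", x$id, alleles, x$age_months,
          x$sex, if (x$treatment == "vpa") ", VPA" else "")
}

#' @export
print.swd_subject <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Construct an EEG recording
#'
#' A single-channel voltage trace in microvolts with its sampling rate.
#' Sample `i` (1-based) covers the half-open interval
#' `[(i-1)/rate, i/rate)` seconds from recording start, so event times
#' derived from sample indices are unambiguous.
#'
#' @param samples Numeric vector of voltages (microvolts); must be finite.
#' @param sampling_rate_hz Sampling rate in Hz (default 1000).
#' @param subject Optional [subject_info()] object.
#' @param start_offset_s Time of the first sample relative to session
#'   start (seconds).
#' @param state_labels Optional character vector of per-epoch vigilance
#'   labels (`"awake"`, `"nrem"`, `"rem"`) tiling the whole duration.
#' @param epoch_length_s Epoch length in seconds for `state_labels`.
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(rnorm(2000), 1000)
#' recording_duration(rec)
#' @export
eeg_recording <- function(samples, sampling_rate_hz = 1000, subject = NULL,
                          start_offset_s = 0, state_labels = NULL,
                          epoch_length_s = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) abort("`samples` must be non-empty.")
  bad <- which(!is.finite(samples))
  if (length(bad) > 0L) {
    abort(sprintf("non-finite sample at index %d (first of %d).",
                  bad[[1L]], length(bad)))
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    abort("`sampling_rate_hz` must be a positive number.")
  }
  if (!is.null(subject) && !inherits(subject, "swd_subject")) {
    abort("`subject` must be created with subject_info().")
  }
  duration_s <- length(samples) / sampling_rate_hz
  if (!is.null(state_labels)) {
    if (is.null(epoch_length_s) || epoch_length_s <= 0) {
      abort("`epoch_length_s` must accompany `state_labels`.")
    }
    ok <- state_labels %in% c("awake", "nrem", "rem")
    if (!all(ok)) {
      abort(sprintf("unknown state label '%s'.", state_labels[!ok][[1L]]))
    }
    if (length(state_labels) != ceiling(duration_s / epoch_length_s - 1e-9)) {
      abort("`state_labels` must tile the full recording duration.")
    }
  }
  structure(
    list(samples = samples, sampling_rate_hz = as.numeric(sampling_rate_hz),
         subject = subject, start_offset_s = as.numeric(start_offset_s),
         state_labels = state_labels, epoch_length_s = epoch_length_s),
    class = "eeg_recording"
  )
}

#' Recording duration in seconds
#' @param rec An [eeg_recording()].
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  length(rec$samples) / rec$sampling_rate_hz
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: %.6g s at %g Hz (%d samples)%s>\n",
              recording_duration(x), x$sampling_rate_hz, length(x$samples),
              if (is.null(x$state_labels)) "" else ", state labels"))
  if (!is.null(x$subject)) cat(" ", format(x$subject), "\n")
  invisible(x)
}

# extract samples covering [start_s, end_s) relative to recording start
slice_samples <- function(rec, start_s, end_s) {
  r <- rec$sampling_rate_hz
  i0 <- floor((start_s - rec$start_offset_s) * r) + 1L
  i1 <- ceiling((end_s - rec$start_offset_s) * r)
  if (i0 < 1L || i1 > length(rec$samples) || i1 < i0) {
    abort(sprintf("interval [%g, %g) lies outside the recording.",
                  start_s, end_s))
  }
  rec$samples[i0:i1]
}

#' Per-epoch vigilance state table
#'
#' Expand a recording's ground-truth state labels into a tidy epoch table.
#'
#' @param rec An [eeg_recording()] carrying `state_labels`.
#' @return A tibble with columns `state`, `start_s`, `end_s` (half-open).
#' @export
state_epochs <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(rec$state_labels)) abort("recording carries no state labels.")
  n <- length(rec$state_labels)
  len <- rec$epoch_length_s
  tibble(
    state = rec$state_labels,
    start_s = rec$start_offset_s + (seq_len(n) - 1L) * len,
    end_s = pmin(rec$start_offset_s + seq_len(n) * len,
                 rec$start_offset_s + recording_duration(rec))
  )
}

#' Construct an event table
#'
#' Events are half-open intervals `[start_s, end_s)` in seconds from
#' recording start. This is the common currency of the package: the
#' detector, the generator's ground truth and all statistics stages
#' exchange tibbles of this shape.
#'
#' @param start_s,end_s Numeric vectors of interval bounds (seconds).
#' @param label Character label per event (recycled).
#' @param ... Further per-event columns (e.g. `dominant_freq_hz`).
#' @return A tibble with at least `start_s`, `end_s`, `label`,
#'   `duration_s`, sorted by start.
#' @examples
#' event_table(c(10, 20), c(13, 22.5))
#' @export
event_table <- function(start_s = numeric(), end_s = numeric(),
                        label = "swd", ...) {
  if (length(start_s) != length(end_s)) {
    abort("`start_s` and `end_s` must have equal length.")
  }
  if (any(end_s <= start_s)) {
    abort(sprintf("event %d has end_s <= start_s.",
                  which(end_s <= start_s)[[1L]]))
  }
  out <- tibble(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                label = rep_len(as.character(label), length(start_s)),
                duration_s = as.numeric(end_s - start_s), ...)
  dplyr::arrange(out, .data$start_s)
}

# indices (i, i+1) of the first overlapping pair in a sorted event table,
# or NULL when none overlap under the half-open convention
first_overlap <- function(events) {
  if (nrow(events) < 2L) return(NULL)
  i <- which(events$start_s[-1L] < events$end_s[-nrow(events)])
  if (length(i) == 0L) NULL else c(i[[1L]], i[[1L]] + 1L)
}
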