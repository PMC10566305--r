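# Per-event spectral characterization, per-session summaries and
# stimulus-locked interruption classification.

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann-windowed segments of
#' `segment_s` seconds with 50% overlap, one-sided density scaling.
#' With 1 s segments the frequency resolution is 1 Hz.
#'
#' @param x Numeric samples.
#' @param rate_hz Sampling rate (Hz).
#' @param segment_s Segment length (s); shortened to the signal length
#'   when the signal is briefer.
#' @param overlap Fractional overlap (default 0.5).
#' @return A tibble with `freq_hz` and `power` (one-sided density).
#' @export
welch_psd <- function(x, rate_hz, segment_s = 1, overlap = 0.5) {
  n <- length(x)
  if (n < 8L) abort("signal too short for a spectrum.")
  nseg <- min(round(segment_s * rate_hz), n)
  step <- max(1L, round(nseg * (1 - overlap)))
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(nseg) - 1L) / (nseg - 1L)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * win
    acc <- acc + Mod(fft(seg))^2
  }
  acc <- acc / (length(starts) * rate_hz * sum(win^2))
  half <- seq_len(floor(nseg / 2) + 1L)
  pw <- acc[half]
  if (length(half) > 2L) pw[2:(length(half) - 1L)] <- 2 * pw[2:(length(half) - 1L)]
  tibble(freq_hz = (half - 1L) * rate_hz / nseg, power = pw)
}

#' Power spectrum of one event
#'
#' Welch periodogram of the recording samples inside a half-open
#' interval (1 s Hann segments, 50% overlap, so the resolution is at
#' most 1 Hz).
#'
#' @param rec An [eeg_recording()].
#' @param start_s,end_s Interval bounds (s); must lie inside the
#'   recording and span at least 1 s.
#' @return A tibble with `freq_hz` and `power`.
#' @export
event_psd <- function(rec, start_s, end_s) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (end_s - start_s < 1) abort("event interval must span at least 1 s.")
  welch_psd(slice_samples(rec, start_s, end_s), rec$sampling_rate_hz)
}

#' Dominant frequency of a spectrum
#'
#' Frequency of the spectral maximum within a band. A flat spectrum
#' has no meaningful peak; the lower band edge is returned with a
#' warning.
#'
#' @param psd Spectrum tibble (`freq_hz`, `power`).
#' @param band Length-2 search band (Hz, default 5-32).
#' @return Peak frequency (Hz).
#' @export
dominant_frequency <- function(psd, band = c(5, 32)) {
  sel <- psd[psd$freq_hz >= band[[1L]] & psd$freq_hz <= band[[2L]], ]
  if (nrow(sel) == 0L) abort("band contains no spectral bins.")
  if (diff(range(sel$power)) == 0) {
    warn("flat spectrum in band; returning the lower band edge.")
    return(band[[1L]])
  }
  sel$freq_hz[[which.max(sel$power)]]
}

#' First-harmonic power ratio
#'
#' Power integrated over `2 f0 +/- halfwidth` divided by power over
#' `f0 +/- halfwidth`. A spiky (spike-and-wave) cycle shape shows a
#' prominent first harmonic, so this ratio separates SWDs from smooth
#' background oscillations.
#'
#' @param psd Spectrum tibble (`freq_hz`, `power`).
#' @param f0 Fundamental frequency (Hz).
#' @param halfwidth_hz Half-width of the integration bands (Hz).
#' @return The power ratio; `Inf` with a warning when the fundamental
#'   band holds no power.
#' @export
harmonic_ratio <- function(psd, f0, halfwidth_hz = 1) {
  if (2 * f0 + halfwidth_hz > max(psd$freq_hz)) {
    abort("spectrum does not cover the first harmonic.")
  }
  band_int <- function(lo, hi) {
    sel <- psd[psd$freq_hz >= lo & psd$freq_hz <= hi, ]
    if (nrow(sel) < 2L) return(sum(sel$power))
    sum(diff(sel$freq_hz) * (head(sel$power, -1) + tail(sel$power, -1)) / 2)
  }
  num <- band_int(2 * f0 - halfwidth_hz, 2 * f0 + halfwidth_hz)
  den <- band_int(f0 - halfwidth_hz, f0 + halfwidth_hz)
  if (den == 0) {
    warn("no power at the fundamental; harmonic ratio is infinite.")
    return(Inf)
  }
  num / den
}

#' Per-session SWD summary statistics
#'
#' Event count per hour, accumulated SWD time per hour, median event
#' duration, and a 1 s-binned duration histogram
#' (`[1,2), [2,3), ..., [10, Inf)`). Per-hour figures are normalized to
#' total recording time.
#'
#' @param events Event tibble.
#' @param recording_h Recording duration in hours.
#' @return One-row tibble with `n_events`, `recording_h`,
#'   `events_per_h`, `accumulated_s_per_h`, `median_duration_s` (`NA`
#'   when there are no events) and a `duration_histogram` list-column.
#' @examples
#' session_statistics(event_table(c(0, 10, 20), c(1, 12, 23)), 1)
#' @export
session_statistics <- function(events, recording_h) {
  if (recording_h <= 0) abort("`recording_h` must be positive.")
  d <- events$duration_s %||% (events$end_s - events$start_s)
  tibble(
    n_events = nrow(events),
    recording_h = recording_h,
    events_per_h = nrow(events) / recording_h,
    accumulated_s_per_h = sum(d) / recording_h,
    median_duration_s = if (length(d) == 0L) NA_real_ else median(d),
    duration_histogram = list(duration_histogram(events))
  )
}

#' Length-sorted duration histogram
#'
#' Event counts in whole-second duration bins `[1,2)` through `[9,10)`
#' plus an open last bin `[10, Inf)`.
#'
#' @param events Event tibble.
#' @return Tibble with `bin_lo_s`, `bin_hi_s`, `count`.
#' @export
duration_histogram <- function(events) {
  d <- events$duration_s %||% (events$end_s - events$start_s)
  lo <- 1:10
  hi <- c(2:10, Inf)
  count <- vapply(seq_along(lo),
                  function(i) sum(d >= lo[[i]] & d < hi[[i]]), integer(1))
  tibble(bin_lo_s = lo, bin_hi_s = hi, count = count)
}

#' Classify stimulus interruption of SWDs
#'
#' An event counts as stimulated when at least one stimulus onset falls
#' inside it (`[start_s, end_s)`); the experimenter triggered tones on
#' live SWD detection, so only in-event onsets qualify. Taking the
#' first such onset `t*`, the event is Case 1 (interrupted) when it
#' ends within `window_s` of the stimulus, Case 2 (resistant)
#' otherwise. Unstimulated events are flagged and excluded from the
#' Case-2 ratio `n2 / (n1 + n2)`.
#'
#' @param events Event tibble.
#' @param stim A [stimulus_log()].
#' @param window_s Interruption latency window (s, default 1.5).
#' @return An object of class `swd_interruption`; see [tidy()] for the
#'   per-event table and [glance()] for the ratio.
#' @export
classify_interruption <- function(events, stim, window_s = 1.5) {
  stopifnot(inherits(stim, "stimulus_log"))
  ev <- as_tibble(events)
  n <- nrow(ev)
  first_onset <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    hit <- stim$onsets_s[stim$onsets_s >= ev$start_s[[i]] &
                         stim$onsets_s < ev$end_s[[i]]]
    if (length(hit) > 0L) first_onset[[i]] <- hit[[1L]]
  }
  ev$stimulated <- !is.na(first_onset)
  ev$stim_onset_s <- first_onset
  ev$case <- dplyr::case_when(
    !ev$stimulated ~ NA_character_,
    ev$end_s <= first_onset + window_s ~ "case1",
    TRUE ~ "case2"
  )
  n1 <- sum(ev$case == "case1", na.rm = TRUE)
  n2 <- sum(ev$case == "case2", na.rm = TRUE)
  structure(
    list(events = ev, n_case1 = n1, n_case2 = n2,
         n_unstimulated = sum(!ev$stimulated),
         case2_ratio = if (n1 + n2 > 0L) n2 / (n1 + n2) else NA_real_,
         window_s = window_s),
    class = "swd_interruption"
  )
}

#' @export
print.swd_interruption <- function(x, ...) {
  cat(sprintf("<swd_interruption: %d case1, %d case2, %d unstimulated; Case-2 ratio %s>\n",
              x$n_case1, x$n_case2, x$n_unstimulated,
              if (is.na(x$case2_ratio)) "undefined" else
                sprintf("%.3f", x$case2_ratio)))
  invisible(x)
}

#' @export
tidy.swd_interruption <- function(x, ...) x$events

#' @export
glance.swd_interruption <- function(x, ...) {
  tibble(n_case1 = x$n_case1, n_case2 = x$n_case2,
         n_unstimulated = x$n_unstimulated, case2_ratio = x$case2_ratio,
         window_s = x$window_s)
}

#' Case-2 ratio by session half
#'
#' Events are assigned to the first or second half of the session by
#' their start time, and interruption counts are tabulated per half —
#' the layout used to ask whether SWD counts drift across a session.
#'
#' @param events Event tibble.
#' @param stim A [stimulus_log()].
#' @param session_duration_h Session duration (hours).
#' @param window_s Interruption window (s).
#' @return Tibble with one row per half: `half`, `n_events`,
#'   `n_case1`, `n_case2`, `case2_ratio`.
#' @export
case2_ratio_by_half <- function(events, stim, session_duration_h,
                                window_s = 1.5) {
  cls <- tidy(classify_interruption(events, stim, window_s))
  mid <- session_duration_h * 3600 / 2
  cls$half <- ifelse(cls$start_s < mid, "first", "second")
  purrr::map_dfr(c("first", "second"), function(h) {
    sub <- cls[cls$half == h, ]
    n1 <- sum(sub$case == "case1", na.rm = TRUE)
    n2 <- sum(sub$case == "case2", na.rm = TRUE)
    tibble(half = h, n_events = nrow(sub), n_case1 = n1, n_case2 = n2,
           case2_ratio = if (n1 + n2 > 0L) n2 / (n1 + n2) else NA_real_)
  })
}
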