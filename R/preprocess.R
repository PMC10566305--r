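# Conditioning of raw recordings before detection.

#' Zero-phase high-pass filter
#'
#' 4th-order Butterworth high-pass (-3 dB at the cutoff) applied
#' forward and backward, so event boundary timing downstream is not
#' shifted by filter delay. Output length equals input length.
#'
#' @param rec An [eeg_recording()].
#' @param cutoff_hz Cutoff frequency (Hz, default 0.9).
#' @return The filtered [eeg_recording()].
#' @export
highpass <- function(rec, cutoff_hz = 0.9) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (cutoff_hz <= 0 || cutoff_hz >= rec$sampling_rate_hz / 2) {
    abort("`cutoff_hz` must lie in (0, sampling_rate/2).")
  }
  tc <- 1 / (2 * pi * cutoff_hz)
  if (recording_duration(rec) < 3 * tc) {
    warn("recording shorter than 3 filter time constants; edge effects dominate.")
  }
  bf <- signal::butter(4, cutoff_hz / (rec$sampling_rate_hz / 2),
                       type = "high")
  y <- signal::filtfilt(bf, rec$samples)
  rec$samples <- as.numeric(y)
  rec
}

#' Resample a recording
#'
#' Polyphase anti-aliased resampling to a target rate. Non-rational
#' rate ratios are approximated by the nearest small rational with a
#' message. Duration is preserved within one output sample.
#'
#' @param rec An [eeg_recording()].
#' @param target_rate_hz Target sampling rate (Hz, default 1000).
#' @return The resampled [eeg_recording()].
#' @export
resample_recording <- function(rec, target_rate_hz = 1000) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_rate_hz < 128) {
    abort("`target_rate_hz` must cover the 2-64 Hz analysis grid (>= 128 Hz).")
  }
  if (abs(target_rate_hz - rec$sampling_rate_hz) < 1e-9) return(rec)
  ratio <- target_rate_hz / rec$sampling_rate_hz
  frac <- rational_approx(ratio, max_den = 1000L)
  if (abs(frac[[1L]] / frac[[2L]] - ratio) > 1e-12) {
    message(sprintf("resampling ratio approximated as %d/%d.",
                    frac[[1L]], frac[[2L]]))
  }
  y <- resample_pq(rec$samples, frac[[1L]], frac[[2L]])
  n_target <- round(length(rec$samples) * frac[[1L]] / frac[[2L]])
  if (length(y) > n_target) y <- y[seq_len(n_target)]
  if (length(y) < n_target) y <- c(y, rep(y[length(y)], n_target - length(y)))
  eeg_recording(y, rec$sampling_rate_hz * frac[[1L]] / frac[[2L]],
                subject = rec$subject, start_offset_s = rec$start_offset_s,
                state_labels = rec$state_labels,
                epoch_length_s = rec$epoch_length_s)
}

# rational-rate resampling: upsample by p (zero stuffing), FIR low-pass
# at the tighter of the two Nyquist limits (windowed-sinc design via
# signal::fir1), compensate the filter group delay, keep every q-th
# sample
resample_pq <- function(x, p, q) {
  n <- length(x)
  m <- max(p, q)
  taps <- 2L * 10L * m           # even order -> integer group delay
  h <- signal::fir1(taps, 1 / m) * p
  up <- numeric(n * p)
  up[seq(1L, by = p, length.out = n)] <- x
  # edge padding (reflection) so events near the ends are not distorted
  pad <- taps
  up <- c(rev(up[seq_len(pad) + 1L]), up, rev(up[length(up) - seq_len(pad)]))
  y <- stats::convolve(up, rev(h), type = "open")
  delay <- taps / 2L
  y <- y[pad + delay + seq_len(n * p)]
  y[seq(1L, by = q, length.out = floor((length(y) - 1L) / q) + 1L)]
}

# continued-fraction rational approximation p/q of x with q <= max_den
rational_approx <- function(x, max_den = 1000L) {
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(r - a) < 1e-12) break
    r <- 1 / (r - a)
  }
  c(as.integer(p1), as.integer(q1))
}
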