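# Wavelet band-power SWD detection: continuous Morlet transform,
# 5-32 Hz band collapse, robust threshold, run segmentation with the
# 1 s floor, and broadband artifact rejection.

# log2-spaced frequency grid, `voices` points per octave, endpoints
# included
freq_grid <- function(fmin, fmax, voices) {
  f <- 2^seq(log2(fmin), log2(fmax), by = 1 / voices)
  if (abs(f[length(f)] - fmax) > 1e-9) f <- c(f, fmax)
  f
}

# Morlet scale for a target Fourier frequency (standard relation)
morlet_scale <- function(f, omega0) (omega0 + sqrt(2 + omega0^2)) / (4 * pi * f)

# |CWT|^2 per frequency, computed in the Fourier domain; `accumulate`
# receives (index, power vector) so long traces never materialize the
# full time x frequency matrix
cwt_power_engine <- function(x, rate, freqs, omega0, accumulate) {
  n <- length(x)
  if (max(freqs) >= rate / 2) {
    abort("frequency grid exceeds the Nyquist frequency.")
  }
  X <- fft(x)
  k <- 0:(n - 1)
  omega_k <- 2 * pi * rate * ifelse(k <= n / 2, k, k - n) / n
  pos <- omega_k > 0
  for (j in seq_along(freqs)) {
    s <- morlet_scale(freqs[[j]], omega0)
    psi <- numeric(n)
    psi[pos] <- pi^(-1 / 4) * sqrt(2 * pi * s * rate) *
      exp(-0.5 * (s * omega_k[pos] - omega0)^2)
    w <- fft(X * psi, inverse = TRUE) / n
    accumulate(j, Re(w)^2 + Im(w)^2)
  }
  invisible(NULL)
}

#' Continuous Morlet wavelet power
#'
#' Squared modulus of the continuous Morlet wavelet transform on a
#' log-spaced frequency grid. Scales map to Fourier frequencies by the
#' standard Morlet relation, and the normalization places the maximum
#' power of a unit sinusoid at the grid frequency nearest its own.
#'
#' @param rec An [eeg_recording()].
#' @param freqs_hz Frequency grid (Hz); default log-spaced 2-64 Hz at
#'   `voices_per_octave` points per octave.
#' @param omega0 Morlet centre frequency (rad, default 6).
#' @param config Optional [detector_config()] supplying grid defaults.
#' @return An object of class `power_time_series`: list with `times_s`,
#'   `freqs_hz` and the nonnegative `power` matrix (time x frequency,
#'   microvolt^2 units up to the wavelet normalization).
#' @export
cwt_power <- function(rec, freqs_hz = NULL, omega0 = NULL,
                      config = detector_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  freqs_hz <- freqs_hz %||% freq_grid(config$freq_min_hz, config$freq_max_hz,
                                      config$voices_per_octave)
  omega0 <- omega0 %||% config$wavelet_omega0
  if (any(diff(freqs_hz) <= 0)) abort("`freqs_hz` must be strictly increasing.")
  n <- length(rec$samples)
  pow <- matrix(0, nrow = n, ncol = length(freqs_hz))
  cwt_power_engine(rec$samples, rec$sampling_rate_hz, freqs_hz, omega0,
                   function(j, p) pow[, j] <<- p)
  structure(
    list(times_s = rec$start_offset_s + (seq_len(n) - 1L) / rec$sampling_rate_hz,
         freqs_hz = freqs_hz, power = pow),
    class = "power_time_series"
  )
}

#' @export
print.power_time_series <- function(x, ...) {
  cat(sprintf("<power_time_series: %d samples x %d frequencies (%.3g-%.3g Hz)>\n",
              length(x$times_s), length(x$freqs_hz), min(x$freqs_hz),
              max(x$freqs_hz)))
  invisible(x)
}

# trapezoidal quadrature weights over the grid points inside [low, high]
band_weights <- function(freqs, low, high) {
  idx <- which(freqs >= low - 1e-9 & freqs <= high + 1e-9)
  if (length(idx) == 0L) abort("band contains no grid frequencies.")
  f <- freqs[idx]
  w <- numeric(length(f))
  if (length(f) > 1L) {
    df <- diff(f)
    w <- c(df[1L] / 2, (df[-1L] + df[-length(df)]) / 2,
           df[length(df)] / 2)
  } else w <- 1
  list(idx = idx, w = w)
}

#' Collapse wavelet power to a band-power trace
#'
#' Trapezoidal integral of the power surface over the grid frequencies
#' inside `[low_hz, high_hz]`, yielding the total in-band spectral
#' power as a function of time. This trace is what the detector
#' thresholds.
#'
#' @param pts A [cwt_power()] result.
#' @param low_hz,high_hz Band bounds (Hz, default 5-32).
#' @return A tibble with `time_s` and `power`.
#' @export
band_power <- function(pts, low_hz = 5, high_hz = 32) {
  stopifnot(inherits(pts, "power_time_series"))
  if (high_hz <= low_hz) abort("need low_hz < high_hz.")
  bw <- band_weights(pts$freqs_hz, low_hz, high_hz)
  tibble(time_s = pts$times_s,
         power = as.numeric(pts$power[, bw$idx, drop = FALSE] %*% bw$w))
}

#' Robust band-power threshold
#'
#' `median(P) + k * 1.4826 * MAD(P)`: under a Gaussian background the
#' scaled MAD estimates the standard deviation, and both statistics
#' tolerate event contamination of up to half the samples, so the
#' threshold barely moves even in severely affected sessions.
#'
#' @param power Band-power trace (numeric, or the tibble from
#'   [band_power()]).
#' @param k Multiplier (default 6).
#' @return The threshold (scalar).
#' @export
compute_threshold <- function(power, k = 6) {
  if (is.data.frame(power)) power <- power$power
  if (length(power) == 0L) abort("empty band-power trace.")
  m <- mad(power)   # includes the 1.4826 Gaussian consistency factor
  if (m == 0) warn("constant band-power trace; threshold equals the median.")
  median(power) + k * m
}

#' Segment supra-threshold runs into candidate events
#'
#' Maximal runs with `power > threshold` become half-open candidate
#' intervals; candidates separated by a gap shorter than `merge_gap_s`
#' are merged (the gap is absorbed), and candidates shorter than
#' `min_duration_s` are discarded — a spike train lasting under 1 s is
#' not counted as an SWD.
#'
#' @param power Band-power trace (numeric vector).
#' @param threshold Scalar threshold.
#' @param rate_hz Sampling rate of the trace (Hz).
#' @param merge_gap_s Merge gap (s).
#' @param min_duration_s Duration floor (s).
#' @param t0 Time of the first trace sample (s).
#' @return An event tibble (sorted, non-overlapping).
#' @export
segment_events <- function(power, threshold, rate_hz, merge_gap_s = 0.3,
                           min_duration_s = 1.0, t0 = 0) {
  if (!is.finite(threshold)) abort("`threshold` must be finite.")
  above <- power > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (length(keep) == 0L) return(event_table())
  # sample i covers [(i-1)/rate, i/rate)
  s <- t0 + (starts[keep] - 1L) / rate_hz
  e <- t0 + ends[keep] / rate_hz
  merged_s <- s[1L]; merged_e <- e[1L]
  if (length(s) > 1L) {
    for (i in 2:length(s)) {
      last <- length(merged_e)
      if (s[[i]] - merged_e[[last]] < merge_gap_s) {
        merged_e[[last]] <- e[[i]]
      } else {
        merged_s <- c(merged_s, s[[i]]); merged_e <- c(merged_e, e[[i]])
      }
    }
  }
  keep2 <- (merged_e - merged_s) >= min_duration_s
  event_table(merged_s[keep2], merged_e[keep2])
}

#' Reject broadband artifact intervals
#'
#' Mechanical noise (cable taps, chewing) is a broadband transient,
#' while spike-wave power stays below ~32 Hz. An interval is rejected
#' when its power integrated over the artifact band (default 40-80 Hz)
#' exceeds `artifact_power_ratio` times its power over the analysis
#' band (5-32 Hz).
#'
#' @param rec The conditioned [eeg_recording()] the intervals refer to.
#' @param intervals Event tibble of candidate intervals.
#' @param config A [detector_config()].
#' @return List with `kept` and `rejected` event tibbles.
#' @export
reject_artifacts <- function(rec, intervals, config = detector_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(intervals) == 0L) {
    return(list(kept = event_table(), rejected = event_table()))
  }
  tr <- detection_traces(rec$samples, rec$sampling_rate_hz, config)
  flag <- artifact_flags(tr, intervals, rec, config)
  list(kept = intervals[!flag, ], rejected = intervals[flag, ])
}

# band and artifact-band power traces, accumulated without the full
# time x frequency matrix
detection_traces <- function(x, rate, config) {
  grid_main <- freq_grid(config$freq_min_hz, config$freq_max_hz,
                         config$voices_per_octave)
  grid_art <- freq_grid(config$artifact_band_hz[[1L]],
                        config$artifact_band_hz[[2L]],
                        config$voices_per_octave)
  bw_main <- band_weights(grid_main, config$band_low_hz, config$band_high_hz)
  all_freqs <- c(grid_main[bw_main$idx], grid_art)
  bw_art <- band_weights(grid_art, config$artifact_band_hz[[1L]],
                         config$artifact_band_hz[[2L]])
  n_main <- length(bw_main$idx)
  band <- numeric(length(x)); art <- numeric(length(x))
  cwt_power_engine(x, rate, all_freqs, config$wavelet_omega0, function(j, p) {
    if (j <= n_main) band <<- band + bw_main$w[[j]] * p
    else art <<- art + bw_art$w[[j - n_main]] * p
  })
  list(band = band, artifact = art, rate = rate)
}

artifact_flags <- function(traces, intervals, rec, config) {
  vapply(seq_len(nrow(intervals)), function(i) {
    i0 <- floor((intervals$start_s[[i]] - rec$start_offset_s) * traces$rate) + 1L
    i1 <- min(ceiling((intervals$end_s[[i]] - rec$start_offset_s) * traces$rate),
              length(traces$band))
    idx <- max(i0, 1L):i1
    sum(traces$artifact[idx]) >
      config$artifact_power_ratio * sum(traces$band[idx])
  }, logical(1))
}

#' Detect spike-wave discharges
#'
#' The full offline pipeline: zero-phase 0.9 Hz high-pass, anti-aliased
#' decimation to the analysis rate, Morlet wavelet transform, 5-32 Hz
#' band-power collapse, robust median + k MAD threshold, run
#' segmentation with gap merging and the 1 s duration floor, broadband
#' artifact rejection, and per-event spectral characterization.
#'
#' @param rec An [eeg_recording()] of at least 10 s.
#' @param config A [detector_config()].
#' @return An event tibble of class `swd_events` with columns
#'   `start_s`, `end_s`, `label`, `duration_s`, `dominant_freq_hz`,
#'   `harmonic_ratio`, `mean_band_power`; attributes carry the
#'   threshold, the rejected intervals and the recording duration.
#' @examples
#' ses <- generate_session(swd_preset("ko"), duration_h = 0.02, seed = 1)
#' detect_swd(ses$recording)
#' @export
detect_swd <- function(rec, config = detector_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (recording_duration(rec) < 10) abort("recording must be at least 10 s.")
  if (config$apply_highpass) rec <- highpass(rec, config$highpass_hz)
  if (rec$sampling_rate_hz > config$analysis_rate_hz) {
    rec <- resample_recording(rec, config$analysis_rate_hz)
  }
  rate <- rec$sampling_rate_hz
  tr <- detection_traces(rec$samples, rate, config)
  theta <- compute_threshold(tr$band, config$threshold_k)
  cand <- segment_events(tr$band, theta, rate,
                         merge_gap_s = config$merge_gap_s,
                         min_duration_s = config$min_duration_s,
                         t0 = rec$start_offset_s)
  flag <- if (nrow(cand) > 0L) artifact_flags(tr, cand, rec, config) else
    logical(0)
  kept <- cand[!flag, ]
  rejected <- cand[flag, ]

  out <- kept
  out$dominant_freq_hz <- NA_real_
  out$harmonic_ratio <- NA_real_
  out$mean_band_power <- NA_real_
  for (i in seq_len(nrow(out))) {
    seg <- slice_samples(rec, out$start_s[[i]], out$end_s[[i]])
    psd <- welch_psd(seg, rate)
    f0 <- dominant_frequency(psd, band = c(config$band_low_hz,
                                           config$band_high_hz))
    out$dominant_freq_hz[[i]] <- f0
    out$harmonic_ratio[[i]] <- harmonic_ratio(psd, f0)
    i0 <- floor((out$start_s[[i]] - rec$start_offset_s) * rate) + 1L
    i1 <- min(ceiling((out$end_s[[i]] - rec$start_offset_s) * rate),
              length(tr$band))
    out$mean_band_power[[i]] <- mean(tr$band[i0:i1])
  }
  structure(out,
            class = c("swd_events", class(tibble())),
            threshold = theta,
            frac_supra = mean(tr$band > theta),
            rejected = rejected,
            recording_h = recording_duration(rec) / 3600,
            detector_config = config)
}

#' Interval-level detection quality against ground truth
#'
#' Greedy one-to-one matching between predicted and true intervals: a
#' pair matches when midpoints lie within `tolerance_s` or when the
#' overlap covers at least half of the shorter interval. Standard
#' precision/recall/F1 follow from the matching.
#'
#' @param predicted,truth Sorted, non-overlapping event tibbles.
#' @param tolerance_s Midpoint tolerance (s, default 0.5).
#' @return One-row tibble: `precision`, `recall`, `f1`, `n_matched`,
#'   `n_predicted`, `n_truth`, `degenerate` (TRUE when a rate was
#'   undefined and reported as 0).
#' @export
detection_metrics <- function(predicted, truth, tolerance_s = 0.5) {
  np <- nrow(predicted); nt <- nrow(truth)
  matched_p <- logical(np)
  n_matched <- 0L
  for (i in seq_len(nt)) {
    ts <- truth$start_s[[i]]; te <- truth$end_s[[i]]
    tm <- (ts + te) / 2
    best <- NA_integer_; best_d <- Inf
    for (j in seq_len(np)) {
      if (matched_p[[j]]) next
      pm <- (predicted$start_s[[j]] + predicted$end_s[[j]]) / 2
      ov <- min(te, predicted$end_s[[j]]) - max(ts, predicted$start_s[[j]])
      shorter <- min(te - ts, predicted$end_s[[j]] - predicted$start_s[[j]])
      if (abs(pm - tm) <= tolerance_s || ov >= 0.5 * shorter) {
        if (abs(pm - tm) < best_d) { best <- j; best_d <- abs(pm - tm) }
      }
    }
    if (!is.na(best)) { matched_p[[best]] <- TRUE; n_matched <- n_matched + 1L }
  }
  degenerate <- np == 0L || nt == 0L
  precision <- if (np == 0L) 0 else n_matched / np
  recall <- if (nt == 0L) 0 else n_matched / nt
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble(precision = precision, recall = recall, f1 = f1,
         n_matched = n_matched, n_predicted = np, n_truth = nt,
         degenerate = degenerate)
}
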