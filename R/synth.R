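# Synthetic rodent-EEG session generator: vigilance-state backgrounds,
# spike-wave discharges with phase-locked harmonics, broadband
# artifacts, and exact ground-truth annotations.

#' Sample a vigilance-state sequence
#'
#' Semi-Markov chain over awake / NREM / REM. Dwell times are
#' exponential with the configured means, rounded up to whole epochs.
#' Sessions start awake; wake is followed by NREM; NREM is followed by
#' REM with probability `nrem_to_rem_prob`, otherwise by wake; REM is
#' always followed by wake (REM is entered only from NREM).
#'
#' @param config A [generator_config()].
#' @param duration_h Session length in hours.
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @return A tibble with one row per epoch: `epoch`, `state`,
#'   `start_s`, `end_s`.
#' @export
sample_state_sequence <- function(config, duration_h, seed = NULL) {
  with_seed_(seed, sample_state_sequence_impl(config, duration_h))
}

sample_state_sequence_impl <- function(config, duration_h) {
  stopifnot(inherits(config, "generator_config"), duration_h > 0)
  len <- config$epoch_length_s
  n_epochs <- ceiling(duration_h * 3600 / len - 1e-9)
  states <- character(0)
  cur <- "awake"
  while (length(states) < n_epochs) {
    m <- config$state_dwell_means_s[[cur]]
    dwell <- if (is.finite(m)) rexp(1L, 1 / m) else Inf
    if (!is.finite(dwell)) {
      states <- c(states, rep(cur, n_epochs - length(states)))
      break
    }
    states <- c(states, rep(cur, max(1L, ceiling(dwell / len))))
    cur <- switch(cur,
                  awake = "nrem",
                  nrem = if (runif(1L) < config$nrem_to_rem_prob) "rem"
                         else "awake",
                  rem = "awake")
  }
  states <- states[seq_len(n_epochs)]
  tibble(epoch = seq_len(n_epochs), state = states,
         start_s = (seq_len(n_epochs) - 1) * len,
         end_s = pmin(seq_len(n_epochs) * len, duration_h * 3600))
}

#' Synthesize state-dependent background EEG
#'
#' Each vigilance state contributes a narrowband oscillator at its
#' configured dominant frequency and amplitude (a sinusoid with slow
#' random phase diffusion, so spectral peaks have realistic finite
#' width), cross-faded over 1 s at state boundaries, plus a pink (1/f)
#' noise floor shared by all states.
#'
#' @param states Epoch tibble from [sample_state_sequence()].
#' @param config A [generator_config()].
#' @param rate_hz Sampling rate (defaults to the config rate).
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @return Numeric vector of samples (microvolts).
#' @export
synth_background <- function(states, config, rate_hz = config$sampling_rate_hz,
                             seed = NULL) {
  with_seed_(seed, synth_background_impl(states, config, rate_hz))
}

synth_background_impl <- function(states, config, rate_hz) {
  stopifnot(inherits(config, "generator_config"))
  total_s <- max(states$end_s)
  n <- round(total_s * rate_hz)
  out <- numeric(n)
  r <- rle(states$state)
  ends <- cumsum(r$lengths)
  run <- tibble(state = r$values,
                start_s = states$start_s[ends - r$lengths + 1L],
                end_s = states$end_s[ends])
  hw <- round(0.5 * rate_hz)            # half of the 1 s cross-fade
  n_runs <- nrow(run)
  phase_diff_sd <- sqrt(0.5 / rate_hz)  # rad per sample; ~0.16 Hz linewidth
  for (k in seq_len(n_runs)) {
    i0 <- floor(run$start_s[[k]] * rate_hz) + 1L
    i1 <- round(run$end_s[[k]] * rate_hz)
    a <- if (k > 1L) i0 - hw else i0
    b <- if (k < n_runs) i1 + hw else i1
    m <- b - a + 1L
    amp <- config$background_amplitudes_uv[[run$state[[k]]]]
    if (amp > 0) {
      f <- config$background_peaks_hz[[run$state[[k]]]]
      t <- (seq.int(a, b) - 1L) / rate_hz
      phase <- 2 * pi * f * t + runif(1L, 0, 2 * pi) +
        cumsum(rnorm(m, 0, phase_diff_sd))
      sig <- amp * sin(phase)
      w <- rep(1, m)
      L <- 2L * hw
      if (k > 1L) w[seq_len(L)] <- 0.5 * (1 - cos(pi * (seq_len(L) - 1L) / (L - 1L)))
      if (k < n_runs) w[m - L + seq_len(L)] <-
          0.5 * (1 + cos(pi * (seq_len(L) - 1L) / (L - 1L)))
      out[a:b] <- out[a:b] + sig * w
    }
  }
  if (config$pink_noise_amplitude_uv > 0) {
    out <- out + pink_noise(n, rate_hz, config$pink_noise_amplitude_uv)
  }
  out
}

# 1/f-amplitude noise via spectral shaping of white Gaussian noise,
# scaled to the requested RMS; flat below 0.1 Hz to keep power finite
pink_noise <- function(n, rate_hz, rms_uv) {
  if (n < 2L) return(numeric(n))
  X <- fft(rnorm(n))
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) * rate_hz / n
  shape <- 1 / sqrt(pmax(f, 0.1))
  shape[1L] <- 0
  x <- Re(fft(X * shape, inverse = TRUE)) / n
  x * rms_uv / sd(x)
}

#' Synthesize one spike-wave discharge waveform
#'
#' A harmonic stack `A * w(t) * sum_k decay^(k-1) cos(2 pi k f0 t)` with
#' all harmonics phase-locked at the crest; the phase alignment is what
#' produces the sharp spike riding each slow-wave cycle and the
#' prominent first-harmonic (2 f0) spectral peak. `w(t)` is a
#' raised-cosine taper at each end of the event.
#'
#' @param duration_s Event duration in seconds (>= 1; the generator
#'   never produces sub-floor events).
#' @param config A [generator_config()].
#' @param rate_hz Sampling rate (defaults to the config rate).
#' @param seed Unused (the waveform is deterministic); accepted for
#'   interface symmetry.
#' @return Numeric vector of samples (microvolts).
#' @export
synth_swd <- function(duration_s, config, rate_hz = config$sampling_rate_hz,
                      seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (duration_s < 1) abort("SWD duration must be >= 1 s.")
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1L) / rate_hz
  ks <- seq_len(config$swd_n_harmonics)
  s <- numeric(n)
  for (k in ks) {
    s <- s + config$swd_harmonic_decay^(k - 1) *
      cos(2 * pi * k * config$swd_f0_hz * t)
  }
  L <- min(round(config$swd_taper_s * rate_hz), floor(n / 2))
  w <- rep(1, n)
  if (L > 0L) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(L) - 0.5) / L))
    w[seq_len(L)] <- ramp
    w[n + 1L - seq_len(L)] <- ramp
  }
  config$swd_amplitude_uv * w * s
}

#' Generate a complete synthetic session with ground truth
#'
#' Assembles a session: state-dependent background, SWDs injected only
#' into awake time (event count Poisson with mean
#' `swd_rate_per_h * awake_hours`, start times uniform over awake time,
#' durations `1 + LogNormal`, overlaps rejected and redrawn), and
#' broadband white-noise artifacts (Poisson anywhere in the session, at
#' five times the SWD amplitude). Ground-truth event, state and
#' artifact tables are returned exactly as drawn.
#'
#' @param config A [generator_config()] or [swd_preset()] output.
#' @param duration_h Session length in hours.
#' @param seed Integer seed; identical `(config, duration_h, seed)`
#'   give bit-identical sessions.
#' @param subject Optional [subject_info()].
#' @return An object of class `swd_session`: list with `recording`
#'   ([eeg_recording()] carrying the true state labels), `events`,
#'   `states`, `artifacts` (tibbles).
#' @examples
#' s <- generate_session(swd_preset("ko"), duration_h = 0.02, seed = 1)
#' nrow(s$events)
#' @export
generate_session <- function(config, duration_h, seed = NULL, subject = NULL) {
  stopifnot(inherits(config, "generator_config"), duration_h > 0)
  with_seed_(seed, {
    rate <- config$sampling_rate_hz
    epochs <- sample_state_sequence_impl(config, duration_h)
    x <- synth_background_impl(epochs, config, rate)
    total_s <- duration_h * 3600

    # contiguous awake runs available for event placement
    r <- rle(epochs$state)
    ends <- cumsum(r$lengths)
    runs <- tibble(state = r$values,
                   start_s = epochs$start_s[ends - r$lengths + 1L],
                   end_s = epochs$end_s[ends])
    awake <- runs[runs$state == "awake", ]
    awake_h <- sum(awake$end_s - awake$start_s) / 3600

    n_ev <- rpois(1L, config$swd_rate_per_h * awake_h)
    starts <- numeric(0); ends_ev <- numeric(0)
    if (n_ev > 0L) {
      durs <- 1 + rlnorm(n_ev, config$swd_duration_lognorm_mu,
                         config$swd_duration_lognorm_sigma)
      for (d in durs) {
        placed <- FALSE
        for (try in seq_len(1000L)) {
          slack <- pmax(awake$end_s - awake$start_s - d, 0)
          if (sum(slack) == 0) next
          j <- sample.int(nrow(awake), 1L, prob = slack)
          s0 <- runif(1L, awake$start_s[[j]], awake$end_s[[j]] - d)
          if (!any(s0 < ends_ev & s0 + d > starts)) {
            starts <- c(starts, s0); ends_ev <- c(ends_ev, s0 + d)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          abort("could not place an SWD without overlap after 1000 draws; lower `swd_rate_per_h` or the duration law.")
        }
      }
      ord <- order(starts)
      starts <- starts[ord]; ends_ev <- ends_ev[ord]
      for (i in seq_along(starts)) {
        wav <- synth_swd(ends_ev[[i]] - starts[[i]], config, rate)
        i0 <- floor(starts[[i]] * rate) + 1L
        idx <- i0:min(i0 + length(wav) - 1L, length(x))
        x[idx] <- x[idx] + wav[seq_along(idx)]
      }
    }
    events <- event_table(starts, ends_ev, label = "swd")

    n_art <- rpois(1L, config$artifact_rate_per_h * duration_h)
    art_start <- sort(runif(n_art, 0, total_s - config$artifact_duration_s))
    for (s0 in art_start) {
      i0 <- floor(s0 * rate) + 1L
      m <- round(config$artifact_duration_s * rate)
      idx <- i0:min(i0 + m - 1L, length(x))
      x[idx] <- x[idx] + rnorm(length(idx), 0, 5 * config$swd_amplitude_uv)
    }
    artifacts <- if (n_art > 0L) {
      event_table(art_start, art_start + config$artifact_duration_s,
                  label = "artifact")
    } else event_table()

    rec <- eeg_recording(x, rate, subject = subject,
                         state_labels = epochs$state,
                         epoch_length_s = config$epoch_length_s)
    structure(list(recording = rec, events = events, states = epochs,
                   artifacts = artifacts, config = config,
                   duration_h = duration_h),
              class = "swd_session")
  })
}

#' @export
print.swd_session <- function(x, ...) {
  cat(sprintf("<swd_session: %.3g h, %d true SWDs, %d artifacts>\n",
              x$duration_h, nrow(x$events), nrow(x$artifacts)))
  invisible(x)
}
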