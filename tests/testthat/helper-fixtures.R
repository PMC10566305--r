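# Shared fixtures, built in code at test time.

# a short all-one-state epoch table
uniform_states <- function(state, duration_s, epoch_length_s = 10) {
  n <- ceiling(duration_s / epoch_length_s)
  tibble::tibble(epoch = seq_len(n), state = state,
                 start_s = (seq_len(n) - 1) * epoch_length_s,
                 end_s = pmin(seq_len(n) * epoch_length_s, duration_s))
}

# a small, cheap session: full generator at a reduced sampling rate
small_session <- function(duration_h = 0.1, seed = 1, rate = 1000, ...) {
  cfg <- swdwave:::config_update(swd_preset("ko"),
                                 c(list(sampling_rate_hz = rate), list(...)))
  generate_session(cfg, duration_h, seed = seed)
}

# brute-force reference segmentation: independent run-length scan used
# as the oracle for segment_events
segment_oracle <- function(power, threshold, rate_hz, merge_gap_s,
                           min_duration_s) {
  above <- power > threshold
  iv <- list()
  i <- 1L
  n <- length(above)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      iv[[length(iv) + 1L]] <- c((i - 1L) / rate_hz, j / rate_hz)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(iv) == 0L) return(event_table())
  merged <- list(iv[[1L]])
  for (k in seq_along(iv)[-1L]) {
    last <- merged[[length(merged)]]
    if (iv[[k]][1L] - last[2L] < merge_gap_s) {
      merged[[length(merged)]][2L] <- iv[[k]][2L]
    } else merged[[length(merged) + 1L]] <- iv[[k]]
  }
  keep <- Filter(function(v) v[2L] - v[1L] >= min_duration_s, merged)
  if (length(keep) == 0L) return(event_table())
  event_table(vapply(keep, `[`, numeric(1), 1L),
              vapply(keep, `[`, numeric(1), 2L))
}
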