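cfg <- generator_config()

test_that("state sequences are deterministic and respect the chain topology", {
  a <- sample_state_sequence(cfg, duration_h = 2, seed = 3)
  b <- sample_state_sequence(cfg, duration_h = 2, seed = 3)
  expect_identical(a, b)
  expect_equal(nrow(a), 720L)          # 2 h of 10 s epochs
  expect_equal(a$state[[1L]], "awake") # sessions start awake
  # REM entered only from NREM, wake only followed by NREM
  tr <- unique(cbind(head(a$state, -1), tail(a$state, -1)))
  tr <- tr[tr[, 1] != tr[, 2], , drop = FALSE]
  for (i in seq_len(nrow(tr))) {
    expect_true(paste(tr[i, ], collapse = ">") %in%
                  c("awake>nrem", "nrem>rem", "nrem>awake", "rem>awake"))
  }
})

test_that("an infinite awake dwell yields an all-awake sequence", {
  cfg_inf <- generator_config(state_dwell_means_s = c(awake = Inf, nrem = 180,
                                                      rem = 60))
  s <- sample_state_sequence(cfg_inf, duration_h = 1, seed = 1)
  expect_true(all(s$state == "awake"))
})

test_that("awake dwell times match the configured exponential law", {
  # oracle: mean of an Exp(120) dwell ceiled to 10 s epochs is
  # 10 / (1 - exp(-10/120))
  expected <- 10 / (1 - exp(-10 / 120))
  dwells <- unlist(lapply(1:300, function(s) {
    seq_ <- sample_state_sequence(cfg, duration_h = 1, seed = 1000 + s)
    r <- rle(seq_$state)
    # interior awake runs only (first and last may be truncated)
    keep <- r$values == "awake"
    keep[c(1L, length(keep))] <- FALSE
    r$lengths[keep] * 10
  }))
  expect_gt(length(dwells), 500)
  expect_lt(abs(mean(dwells) - expected) / expected, 0.1)
})

test_that("background spectra peak at the configured state frequencies", {
  nrem <- synth_background(uniform_states("nrem", 120), cfg, seed = 5)
  psd <- welch_psd(nrem, cfg$sampling_rate_hz, segment_s = 2)
  expect_equal(dominant_frequency(psd, band = c(1, 32)), 3, tolerance = 0.25)

  awake <- synth_background(uniform_states("awake", 120), cfg, seed = 5)
  psd_a <- welch_psd(awake, cfg$sampling_rate_hz, segment_s = 2)
  expect_lt(abs(dominant_frequency(psd_a, band = c(15, 60)) - 30), 2)
  # wakefulness is the small-amplitude pattern
  expect_lt(sd(awake), sd(nrem))

  rem <- synth_background(uniform_states("rem", 120), cfg, seed = 5)
  psd_r <- welch_psd(rem, cfg$sampling_rate_hz, segment_s = 2)
  expect_equal(dominant_frequency(psd_r, band = c(1, 32)), 7, tolerance = 0.25)
})

test_that("zero amplitudes produce an all-zero background", {
  cfg0 <- generator_config(background_amplitudes_uv = c(awake = 0, nrem = 0,
                                                        rem = 0),
                           pink_noise_amplitude_uv = 0)
  x <- synth_background(uniform_states("nrem", 60), cfg0, seed = 1)
  expect_equal(max(abs(x)), 0)
})

test_that("SWD waveforms have crest-locked harmonics and the taper", {
  # oracle: closed-form harmonic sum on a fine grid
  th <- seq(0, 2 * pi, length.out = 100000)
  stack <- cos(th) + 0.5 * cos(2 * th) + 0.25 * cos(3 * th)
  crest <- max(stack)    # = 1.75, all cosines at 1
  trough <- min(stack)   # = -0.75 at half cycle
  s <- synth_swd(3, cfg)
  mid <- s[round(length(s) / 3):round(2 * length(s) / 3)]
  expect_equal(max(mid), cfg$swd_amplitude_uv * crest, tolerance = 1e-3)
  expect_equal(min(mid), cfg$swd_amplitude_uv * trough, tolerance = 1e-3)

  # single-harmonic limit: a tapered pure sinusoid
  cfg1 <- generator_config(swd_n_harmonics = 1)
  s1 <- synth_swd(2, cfg1)
  t <- (seq_along(s1) - 1) / cfg1$sampling_rate_hz
  ref <- cfg1$swd_amplitude_uv * cos(2 * pi * 8 * t)
  interior <- t > 0.3 & t < 1.7
  expect_equal(s1[interior], ref[interior], tolerance = 1e-9)
  # taper pulls the edges down
  expect_lt(abs(s1[1]), 0.05 * cfg1$swd_amplitude_uv)

  expect_error(synth_swd(0.8, cfg), ">= 1")
})

test_that("SWD spectra show the fundamental and first harmonic", {
  s <- synth_swd(3, cfg)
  psd <- welch_psd(s, cfg$sampling_rate_hz)
  expect_equal(dominant_frequency(psd, band = c(2, 64)), 8)
  # second-largest local maximum at 16 Hz
  p <- psd$power
  locmax <- which(diff(sign(diff(p))) == -2) + 1L
  locmax <- locmax[order(p[locmax], decreasing = TRUE)]
  expect_equal(psd$freq_hz[locmax[2L]], 16)
})

test_that("sessions are deterministic with exact ground truth", {
  a <- small_session(duration_h = 0.05, seed = 9)
  b <- small_session(duration_h = 0.05, seed = 9)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$events, b$events)

  cfg0 <- swdwave:::config_update(swd_preset("ko"), list(swd_rate_per_h = 0))
  s0 <- generate_session(cfg0, duration_h = 0.05, seed = 2)
  expect_equal(nrow(s0$events), 0L)
})

test_that("truth events respect the floor, wake-only placement and non-overlap", {
  for (seed in 1:4) {
    ses <- small_session(duration_h = 0.2, seed = seed)
    ev <- ses$events
    if (nrow(ev) == 0L) next
    expect_true(all(ev$duration_s >= 1))
    expect_null(swdwave:::first_overlap(ev))
    st <- ses$states
    for (i in seq_len(nrow(ev))) {
      inside <- st$state[st$start_s < ev$end_s[[i]] & st$end_s > ev$start_s[[i]]]
      expect_true(all(inside == "awake"))
    }
  }
})

test_that("event counts follow the configured rate per awake hour", {
  counts <- vapply(1:40, function(s) {
    ses <- small_session(duration_h = 0.5, seed = 400 + s, rate = 250)
    awake_h <- sum(ses$states$state == "awake") * 10 / 3600
    c(nrow(ses$events), awake_h)
  }, numeric(2))
  rate_hat <- sum(counts[1, ]) / sum(counts[2, ])
  expect_lt(abs(rate_hat - swd_preset("ko")$swd_rate_per_h) /
              swd_preset("ko")$swd_rate_per_h, 0.1)
})

test_that("concatenated truth-event samples keep the SWD spectral signature", {
  ses <- small_session(duration_h = 0.2, seed = 11)
  rec <- ses$recording
  segs <- unlist(lapply(seq_len(nrow(ses$events)), function(i) {
    swdwave:::slice_samples(rec, ses$events$start_s[[i]], ses$events$end_s[[i]])
  }))
  psd <- welch_psd(segs, rec$sampling_rate_hz)
  expect_equal(dominant_frequency(psd, band = c(2, 64)), 8, tolerance = 0.5)
  i16 <- which(abs(psd$freq_hz - 16) < 0.6)[1]
  expect_gt(psd$power[i16], psd$power[i16 - 2])
  expect_gt(psd$power[i16], psd$power[i16 + 2])
})
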