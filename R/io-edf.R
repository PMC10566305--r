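# Minimal standard EDF (European Data Format) I/O: 16-bit integer
# encoding, one signal per file, physical dimension "uV", 1 s data
# records. No EDF+ annotation channel.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) abort(sprintf("EDF header field too long: '%s'", x))
  formatC(x, width = width, flag = "-")
}

# render a number into an EDF ASCII field of `width` chars
edf_num <- function(v, width) {
  for (digits in seq(10, 1)) {
    s <- formatC(v, digits = digits, format = "g")
    if (nchar(s) <= width) return(edf_pad(s, width))
  }
  abort("cannot render EDF numeric field.")
}

write_recording_edf <- function(rec, path) {
  rate <- rec$sampling_rate_hz
  if (abs(rate - round(rate)) > 1e-9) {
    abort("EDF writer requires an integer sampling rate.")
  }
  rate <- as.integer(round(rate))
  x <- rec$samples
  spr <- rate                       # one-second data records
  if (length(x) %% spr != 0L) {
    warn("recording padded with zeros to a whole number of seconds for EDF.")
    x <- c(x, numeric(spr - length(x) %% spr))
  }
  n_rec <- length(x) %/% spr
  pmin_ <- min(x); pmax_ <- max(x)
  if (pmax_ - pmin_ < 1e-9) { pmin_ <- pmin_ - 1; pmax_ <- pmax_ + 1 }
  dmin <- -32768; dmax <- 32767
  dig <- as.integer(round((x - pmin_) / (pmax_ - pmin_) * (dmax - dmin) + dmin))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(if (is.null(rec$subject)) "X" else rec$subject$id, 80),
    edf_pad("swdwave", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * 2L, 8),          # header bytes for 1 signal
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_num(1, 8),                  # record duration (s)
    edf_pad(1L, 4),                 # number of signals
    edf_pad("EEG", 16), edf_pad("", 80), edf_pad("uV", 8),
    edf_num(pmin_, 8), edf_num(pmax_, 8),
    edf_pad(dmin, 8), edf_pad(dmax, 8),
    edf_pad("HP:0Hz", 80), edf_pad(spr, 8), edf_pad("", 32)
  )
  writeChar(hdr, con, eos = NULL)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

read_recording_edf <- function(path, subject = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256L, useBytes = TRUE)
  fld <- function(from, len) trimws(substr(hdr, from, from + len - 1L))
  n_rec <- as.integer(fld(237, 8))
  rec_dur <- as.numeric(fld(245, 8))
  ns <- as.integer(fld(253, 4))
  if (is.na(ns) || ns < 1L) abort("malformed EDF header.")
  sig <- readChar(con, 256L * ns, useBytes = TRUE)
  sfld <- function(offset, len, i) {
    from <- offset * ns + (i - 1L) * len + 1L
    trimws(substr(sig, from, from + len - 1L))
  }
  # per-signal blocks: label 16, transducer 80, dim 8, pmin 8, pmax 8,
  # dmin 8, dmax 8, prefilter 80, spr 8, reserved 32
  off <- cumsum(c(0L, 16L, 80L, 8L, 8L, 8L, 8L, 80L, 8L))
  i <- 1L                           # first signal only
  pmin_ <- as.numeric(sfld(off[4], 8L, i))
  pmax_ <- as.numeric(sfld(off[5], 8L, i))
  dmin <- as.numeric(sfld(off[6], 8L, i))
  dmax <- as.numeric(sfld(off[7], 8L, i))
  spr <- as.integer(sfld(off[9], 8L, i))
  spr_all <- vapply(seq_len(ns), function(j) as.integer(sfld(off[9], 8L, j)),
                    integer(1))
  out <- numeric(0)
  chunks <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr_all[j], size = 2L, signed = TRUE,
                   endian = "little")
      if (j == 1L) chunks[[r]] <- d
    }
  }
  d <- unlist(chunks)
  phys <- (d - dmin) * (pmax_ - pmin_) / (dmax - dmin) + pmin_
  eeg_recording(phys, spr / rec_dur, subject = subject)
}

# amplitude resolution of the 16-bit encoding used for a recording
edf_quantization_step <- function(rec) {
  rng <- range(rec$samples)
  if (diff(rng) < 1e-9) rng <- rng + c(-1, 1)
  diff(rng) / 65535
}
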