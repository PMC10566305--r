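# ggplot2 helpers for the main result types.

#' Plot a recording trace with detected events
#'
#' @param rec An [eeg_recording()].
#' @param events Optional event tibble shaded over the trace.
#' @param from_s,to_s Time window to draw (defaults to the first 30 s).
#' @return A ggplot object.
#' @export
plot_recording <- function(rec, events = NULL, from_s = 0,
                           to_s = min(30, recording_duration(rec))) {
  stopifnot(inherits(rec, "eeg_recording"))
  i0 <- max(1L, floor(from_s * rec$sampling_rate_hz) + 1L)
  i1 <- min(length(rec$samples), ceiling(to_s * rec$sampling_rate_hz))
  df <- tibble(time_s = (seq(i0, i1) - 1L) / rec$sampling_rate_hz,
               amplitude_uv = rec$samples[i0:i1])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$amplitude_uv)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "amplitude (µV)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0L) {
    ev <- events[events$end_s > from_s & events$start_s < to_s, ]
    if (nrow(ev) > 0L) {
      p <- p + ggplot2::geom_rect(
        data = ev,
        ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                     ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, fill = "firebrick", alpha = 0.15
      )
    }
  }
  p
}

#' @export
autoplot.power_time_series <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_along(object$times_s),
                           j = seq_along(object$freqs_hz))
  df$time_s <- object$times_s[df$i]
  df$freq_hz <- object$freqs_hz[df$j]
  df$power <- object$power[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$freq_hz,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::scale_fill_viridis_c(name = "power (µV²)") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a length-sorted SWD duration histogram
#'
#' @param events Event tibble (or the output of [duration_histogram()]).
#' @return A ggplot object.
#' @export
plot_duration_histogram <- function(events) {
  h <- if (all(c("bin_lo_s", "count") %in% names(events))) events else
    duration_histogram(events)
  h$bin <- factor(ifelse(is.finite(h$bin_hi_s),
                         sprintf("[%g,%g)", h$bin_lo_s, h$bin_hi_s),
                         sprintf("≥%g", h$bin_lo_s)),
                  levels = ifelse(is.finite(h$bin_hi_s),
                                  sprintf("[%g,%g)", h$bin_lo_s, h$bin_hi_s),
                                  sprintf("≥%g", h$bin_lo_s)))
  ggplot2::ggplot(h, ggplot2::aes(.data$bin, .data$count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "SWD duration (s)", y = "count") +
    ggplot2::theme_minimal()
}
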