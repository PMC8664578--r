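#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot EEG traces
#'
#' Stacked channel traces over a time range, optionally overlaying
#' detected events as shaded spans.
#'
#' @param rec An [eeg_recording()].
#' @param t_lim Time range in seconds (default first 30 s).
#' @param channels Channels to draw (default all).
#' @param events Optional event tibble with `channel` plus either
#'   `onset_s`/`offset_s` or `trough_time_s`/`duration_s`.
#' @param spacing_uV Vertical offset between channels.
#' @return A ggplot object.
#' @export
plot_recording <- function(rec, t_lim = c(0, 30),
                           channels = rec$channel_labels, events = NULL,
                           spacing_uV = 150) {
  rate <- rec$sampling_rate
  idx <- seq(max(1L, round(t_lim[1] * rate) + 1L),
             min(nrow(rec$signal), round(t_lim[2] * rate)))
  df <- purrr::map_dfr(seq_along(channels), function(i) {
    tibble::tibble(
      time_s = (idx - 1) / rate,
      channel = channels[i],
      value = rec$signal[idx, channels[i]] - (i - 1) * spacing_uV
    )
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value,
                                        group = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::scale_y_continuous(
      breaks = -(seq_along(channels) - 1) * spacing_uV,
      labels = channels) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    ev <- events[events$channel %in% channels, ]
    if ("onset_s" %in% names(ev)) {
      ev$start <- ev$onset_s; ev$end <- ev$offset_s
    } else {
      ev$start <- ev$trough_time_s - ev$duration_s / 2
      ev$end <- ev$trough_time_s + ev$duration_s / 2
    }
    ev <- ev[ev$end >= t_lim[1] & ev$start <= t_lim[2], ]
    if (nrow(ev) > 0) {
      p <- p + ggplot2::geom_rect(
        data = ev,
        ggplot2::aes(xmin = .data$start, xmax = .data$end,
                     fill = .data$kind),
        ymin = -Inf, ymax = Inf, alpha = 0.2, inherit.aes = FALSE)
    }
  }
  p
}

#' Plot a hypnogram
#' @param hyp A [hypnogram()].
#' @return A ggplot object (stage vs time step plot, artifacts marked).
#' @export
plot_hypnogram <- function(hyp) {
  df <- dplyr::mutate(hyp, time_h = .data$epoch * 30 / 3600,
                      level = as.integer(factor(.data$stage,
                                                levels = c("N3", "N2", "N1",
                                                           "REM", "W"))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$level)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = df[df$artifact, ], colour = "red",
                        shape = 4) +
    ggplot2::scale_y_continuous(breaks = 1:5,
                                labels = c("N3", "N2", "N1", "REM", "W")) +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of an event-triggered coherogram
#' @param object A `coherogram`.
#' @param f_lim Frequency range to display, Hz.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.coherogram <- function(object, f_lim = c(0, 20), ...) {
  sel <- object$freq_hz >= f_lim[1] & object$freq_hz <= f_lim[2]
  df <- tidyr::expand_grid(time_s = object$time_s,
                           freq_hz = object$freq_hz[sel])
  df$coherence <- as.vector(object$coherence[, sel])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$freq_hz,
                                   fill = .data$coherence)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "time from SW trough (s)", y = "frequency (Hz)",
                  fill = "coherence") +
    ggplot2::theme_minimal()
}

#' Tile plot of a pairwise coherence matrix
#' @param object A `coherence_matrix` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.coherence_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$target, y = .data$seed,
                                       fill = .data$coherence)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "target electrode", y = "seed electrode",
                  fill = "SW coherence") +
    ggplot2::theme_minimal()
}

#' Scree plot of an NREM feature PCA
#' @param object An `nrem_pca`.
#' @param ... Unused.
#' @return A ggplot object (explained variance per component with the
#'   cumulative fraction).
#' @exportS3Method ggplot2::autoplot
autoplot.nrem_pca <- function(object, ...) {
  df <- glance(object)
  df$component <- factor(df$component, levels = df$component)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$explained)) +
    ggplot2::geom_col() +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative, group = 1),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative),
                        colour = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of variance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
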