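# ggplot2 displays for the package's result types.

#' Plot a cochleogram
#'
#' Hair-cell density per 100 um along the cochlear axis.
#'
#' @param object A [bin_cochleogram()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.oto_cochleogram <- function(object, ...) {
  d <- as_tibble(object) |>
    tidyr::pivot_longer(c("ihc_per_100um", "ohc_per_100um"),
                        names_to = "type", values_to = "density") |>
    dplyr::mutate(type = ifelse(.data$type == "ihc_per_100um", "IHC", "OHC"),
                  mid_um = (.data$start_um + .data$end_um) / 2)
  ggplot2::ggplot(d, ggplot2::aes(.data$mid_um, .data$density,
                                  fill = .data$type)) +
    ggplot2::geom_col(position = "dodge", width = diff(object$start_um[1:2]) * 0.9) +
    ggplot2::labs(x = "Distance from apex (um)", y = "Cells per 100 um",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ABR intensity series as a waterfall
#'
#' @param series A long ABR series tibble.
#' @param frequency Which stimulus frequency to show (default: first).
#' @param spacing Vertical offset between traces (uV).
#' @return A ggplot.
#' @export
plot_abr_waterfall <- function(series, frequency = NULL, spacing = 2) {
  frequency <- frequency %||% series$frequency[1]
  d <- dplyr::filter(series, .data$frequency == !!frequency) |>
    dplyr::mutate(offset = .data$voltage_uv +
                    (.data$intensity_db - min(.data$intensity_db)) / 5 * spacing)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_ms, .data$offset,
                                  group = .data$intensity_db)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (ms)", y = "Voltage (uV, offset by intensity)",
                  title = paste("ABR,", frequency)) +
    ggplot2::theme_minimal()
}

#' Plot a DPOAE spectrum
#'
#' @param spectrum One level's spectrum (tibble with `frequency_hz`,
#'   `amplitude_db`, `f1_hz`, `f2_hz`).
#' @return A ggplot with the primaries and the 2f1-f2 position marked.
#' @export
plot_dpoae_spectrum <- function(spectrum) {
  f1 <- spectrum$f1_hz[1]; f2 <- spectrum$f2_hz[1]
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(.data$frequency_hz / 1000,
                               .data$amplitude_db)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = (2 * f1 - f2) / 1000, linetype = 2,
                        colour = "red") +
    ggplot2::geom_vline(xintercept = c(f1, f2) / 1000, linetype = 3) +
    ggplot2::labs(x = "Frequency (kHz)", y = "Amplitude (dB SPL)") +
    ggplot2::theme_minimal()
}

#' Plot a behavior trace with detected freezing bouts
#'
#' @param trace A behavior tibble (`time_s`, `activity`).
#' @param bouts Optional [detect_freezing()] result to shade.
#' @param tone_onset_s Optional tone onset to mark.
#' @return A ggplot.
#' @export
plot_behavior_trace <- function(trace, bouts = NULL, tone_onset_s = NULL) {
  g <- ggplot2::ggplot(trace, ggplot2::aes(.data$time_s, .data$activity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Activity (fraction of pixels)") +
    ggplot2::theme_minimal()
  if (!is.null(bouts) && nrow(bouts) > 0) {
    g <- g + ggplot2::geom_rect(
      data = bouts,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "red", alpha = 0.2)
  }
  tone_onset_s <- tone_onset_s %||% attr(trace, "tone_onset_s")
  if (!is.null(tone_onset_s)) {
    g <- g + ggplot2::geom_vline(xintercept = tone_onset_s, linetype = 2)
  }
  g
}
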