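#' Bode plot of an impedance spectrum
#'
#' Magnitude and phase of the selected channels versus frequency on
#' log axes, faceted magnitude over phase.
#'
#' @param spectrum A wide impedance spectrum tibble (`freq_hz`, complex
#'   `Zin`, `Zbody`, `Zout`, `Z`).
#' @param channels Channels to display (default `Zbody` and `Z`).
#' @return A ggplot object.
#' @export
plot_bode <- function(spectrum, channels = c("Zbody", "Z")) {
  long <- spectrum_long(spectrum, channels)
  dat <- dplyr::bind_rows(
    dplyr::mutate(long, value = Mod(.data$z), panel = "|Z| (Ohm)"),
    dplyr::mutate(long, value = Arg(.data$z) * 180 / pi,
                  panel = "phase (deg)"))
  ggplot2::ggplot(dat, ggplot2::aes(.data$freq_hz, .data$value,
                                    colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Frequency (Hz)", y = NULL, colour = NULL,
                  title = "Impedance spectrum (Bode)")
}

#' Nyquist plot of an impedance spectrum
#'
#' Negative imaginary part against real part; the Debye body branch traces
#' a semicircle.
#'
#' @inheritParams plot_bode
#' @return A ggplot object.
#' @export
plot_nyquist <- function(spectrum, channels = "Zbody") {
  long <- spectrum_long(spectrum, channels)
  ggplot2::ggplot(long, ggplot2::aes(Re(.data$z), -Im(.data$z),
                                     colour = .data$channel)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Re Z (Ohm)", y = "-Im Z (Ohm)", colour = NULL,
                  title = "Impedance spectrum (Nyquist)")
}

#' Plot an FFT amplitude spectrum
#'
#' Level in dB relative to the spectral peak versus frequency, the display
#' used to judge the instrument noise floor.
#'
#' @param spec A tibble from [fft_spectrum()].
#' @return A ggplot object.
#' @export
plot_fft_spectrum <- function(spec) {
  stopifnot(all(c("freq_hz", "level_db") %in% names(spec)))
  dat <- dplyr::filter(spec, .data$freq_hz > 0)
  dat$rel_db <- dat$level_db - max(dat$level_db)
  ggplot2::ggplot(dat, ggplot2::aes(.data$freq_hz, .data$rel_db)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Level (dB re carrier)",
                  title = "FFT amplitude spectrum")
}

spectrum_long <- function(spectrum, channels) {
  cols <- intersect(channels, names(spectrum))
  if (length(cols) == 0) abort("None of the requested channels are present.")
  purrr::map_dfr(cols, function(cc) tibble(
    freq_hz = spectrum$freq_hz, channel = cc, z = spectrum[[cc]]))
}
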