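#' Read and write phantom configurations as YAML
#'
#' The configuration file mirrors the [phantom_config()] fields in SI
#' units, e.g.:
#' ```yaml
#' contact_in:  {R: 1.0e5, C: 1.0e-4}
#' contact_out: {R: 1.0e5, C: 1.0e-4}
#' body_Rinf: 1000
#' body_dR: 10000
#' body_C: 1.0e-5
#' Rref: 100
#' r_tolerance: 0.01
#' c_tolerance: 0.05
#' ```
#' Missing keys fall back to the nominal validation-phantom values.
#'
#' @param path File path.
#' @param cfg A [phantom_config()] (for writing).
#' @return `read_phantom_config()` returns a `phantom_config`;
#'   `write_phantom_config()` returns `path` invisibly.
#' @export
read_phantom_config <- function(path) {
  raw <- yaml::read_yaml(path)
  nominal <- phantom_config()
  rc <- function(key) {
    if (is.null(raw[[key]])) nominal[[key]]
    else parallel_rc(R = raw[[key]]$R, C = raw[[key]]$C %||% 0)
  }
  num <- function(key) as.numeric(raw[[key]] %||% nominal[[key]])
  phantom_config(contact_in = rc("contact_in"), contact_out = rc("contact_out"),
                 body_Rinf = num("body_Rinf"), body_dR = num("body_dR"),
                 body_C = num("body_C"), Rref = num("Rref"),
                 r_tolerance = num("r_tolerance"),
                 c_tolerance = num("c_tolerance"))
}

#' @rdname read_phantom_config
#' @export
write_phantom_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "phantom_config"))
  yaml::write_yaml(list(
    contact_in = list(R = cfg$contact_in$R, C = cfg$contact_in$C),
    contact_out = list(R = cfg$contact_out$R, C = cfg$contact_out$C),
    body_Rinf = cfg$body_Rinf, body_dR = cfg$body_dR, body_C = cfg$body_C,
    Rref = cfg$Rref,
    r_tolerance = cfg$r_tolerance, c_tolerance = cfg$c_tolerance), path)
  invisible(path)
}

#' Read and write impedance spectra as CSV
#'
#' Long CSV dialect: columns `freq_hz`, `channel` (one of `Zin`, `Zbody`,
#' `Zout`, `Z`), `re_ohm`, `im_ohm`. Real/imaginary parts are stored at
#' full double precision, so a write--read round trip is lossless;
#' magnitude and phase for Bode displays are derived on demand.
#'
#' @param spectrum A wide impedance spectrum tibble (`freq_hz`, complex
#'   `Zin`, `Zbody`, `Zout`, `Z`).
#' @param path File path.
#' @return `read_spectrum_csv()` returns the wide spectrum tibble;
#'   `write_spectrum_csv()` returns `path` invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  cols <- c("Zin", "Zbody", "Zout", "Z")
  stopifnot(all(c("freq_hz", cols) %in% names(spectrum)))
  # %.17g guarantees a lossless double round trip through the text file
  long <- purrr::map_dfr(cols, function(cc) tibble(
    freq_hz = sprintf("%.17g", spectrum$freq_hz), channel = cc,
    re_ohm = sprintf("%.17g", Re(spectrum[[cc]])),
    im_ohm = sprintf("%.17g", Im(spectrum[[cc]]))))
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  # base read.csv parses doubles with correctly rounded strtod, preserving
  # the lossless round trip
  long <- as_tibble(utils::read.csv(path))
  stopifnot(all(c("freq_hz", "channel", "re_ohm", "im_ohm") %in% names(long)))
  long$z <- complex(real = long$re_ohm, imaginary = long$im_ohm)
  wide <- tidyr::pivot_wider(long[c("freq_hz", "channel", "z")],
                             names_from = "channel", values_from = "z")
  as_tibble(wide[c("freq_hz", intersect(c("Zin", "Zbody", "Zout", "Z"),
                                        names(wide)))])
}

#' Read and write phasor tables as CSV
#'
#' Long CSV with columns `freq_hz`, `channel` (`u1`..`u4`), `amplitude_v`,
#' `phase_rad`; the complex `phasor` column is reconstructed on read via
#' `amplitude * exp(-1i * phase)`.
#'
#' @param phasors A long phasor tibble from [run_sweep()].
#' @param path File path.
#' @return `read_phasors_csv()` returns the phasor tibble;
#'   `write_phasors_csv()` returns `path` invisibly.
#' @export
write_phasors_csv <- function(phasors, path) {
  stopifnot(all(c("freq_hz", "channel", "amplitude_v", "phase_rad")
                %in% names(phasors)))
  readr::write_csv(
    phasors[c("freq_hz", "channel", "amplitude_v", "phase_rad")], path)
  invisible(path)
}

#' @rdname write_phasors_csv
#' @export
read_phasors_csv <- function(path) {
  out <- as_tibble(utils::read.csv(path))
  stopifnot(all(c("freq_hz", "channel", "amplitude_v", "phase_rad")
                %in% names(out)))
  out$phasor <- out$amplitude_v * exp(-1i * out$phase_rad)
  as_tibble(out)
}

#' Write a waveform block as CSV
#'
#' Columns `t`, `u1`..`u4`; intended for debugging and external analysis.
#'
#' @param block A `waveform_block`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(block, path) {
  stopifnot(inherits(block, "waveform_block"))
  readr::write_csv(as_tibble(block), path)
  invisible(path)
}
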