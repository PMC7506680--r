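#' Four-electrode impedance extraction by voltage comparison
#'
#' Turns measured node phasors into block impedances by comparison against
#' the reference resistor:
#' \deqn{Z_{in}' = R_{ref}\frac{u_1-u_2}{u_4},\quad
#'       Z_{body}' = R_{ref}\frac{u_2-u_3}{u_4},\quad
#'       Z_{out}' = R_{ref}\left(\frac{u_3}{u_4}-1\right),\quad
#'       Z' = R_{ref}\left(\frac{u_1}{u_4}-1\right).}
#' Because every formula is a ratio of (differences of) node voltages, any
#' common complex scale on the four phasors cancels, and the body estimate
#' `Zbody'` is unaffected by the contact impedances — this residual
#' rejection is the method's central property. The identity
#' `Z' = Zin' + Zbody' + Zout'` holds exactly.
#'
#' @param phasors Either a wide phasor table (`freq_hz`, complex
#'   `u1`..`u4`) or the long table produced by [run_sweep()].
#' @param r_ref Reference resistance in ohms.
#' @return An impedance spectrum: tibble with `freq_hz` and complex
#'   columns `Zin`, `Zbody`, `Zout`, `Z` (ohms).
#' @examples
#' ph <- solve_node_phasors(phantom_config(), c(0.01, 1, 100))
#' extract_impedances(ph, r_ref = 100)
#' @export
extract_impedances <- function(phasors, r_ref) {
  if (!is.numeric(r_ref) || r_ref <= 0) abort("`r_ref` must be positive.")
  if ("channel" %in% names(phasors)) phasors <- phasors_wide(phasors)
  stopifnot(all(c("freq_hz", "u1", "u2", "u3", "u4") %in% names(phasors)))
  u4 <- phasors$u4
  if (any(Mod(u4) == 0))
    abort("Degenerate measurement: u4 = 0 at some frequency.")
  tibble(
    freq_hz = phasors$freq_hz,
    Zin = r_ref * (phasors$u1 - phasors$u2) / u4,
    Zbody = r_ref * (phasors$u2 - phasors$u3) / u4,
    Zout = r_ref * (phasors$u3 / u4 - 1),
    Z = r_ref * (phasors$u1 / u4 - 1))
}

#' Average repeated impedance spectra
#'
#' Complex mean per frequency and channel across repeated recordings of
#' the same sweep. All spectra must share the frequency grid.
#'
#' @param spectra A list of impedance spectra (tibbles with `freq_hz` and
#'   complex `Zin`, `Zbody`, `Zout`, `Z`), e.g. repeated
#'   [extract_impedances()] results.
#' @return A spectrum tibble of the same shape; the number of averaged
#'   spectra is recorded in attribute `n_averaged`.
#' @export
average_spectra <- function(spectra) {
  if (inherits(spectra, "data.frame")) spectra <- list(spectra)
  if (length(spectra) == 0) abort("No spectra supplied.")
  cols <- c("Zin", "Zbody", "Zout", "Z")
  f0 <- spectra[[1]]$freq_hz
  for (s in spectra) {
    stopifnot(all(c("freq_hz", cols) %in% names(s)))
    if (length(s$freq_hz) != length(f0) ||
        any(abs(s$freq_hz - f0) > 1e-12 * pmax(f0, 1)))
      abort("All spectra must share the same frequency grid.")
  }
  out <- spectra[[1]]["freq_hz"]
  for (cc in cols) {
    out[[cc]] <- Reduce(`+`, lapply(spectra, `[[`, cc)) / length(spectra)
  }
  structure(as_tibble(out), n_averaged = length(spectra))
}
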