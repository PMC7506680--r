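#' Relative-error spectra against the theoretical phantom
#'
#' Per-frequency relative errors of a measured impedance spectrum against
#' the closed-form phantom values,
#' \eqn{\epsilon = 100\,|Z' - Z| / |Z|} (percent), for each of the four
#' blocks. The complex difference magnitude is used, so both amplitude and
#' phase deviations contribute.
#'
#' @param measured An impedance spectrum tibble (`freq_hz`, complex `Zin`,
#'   `Zbody`, `Zout`, `Z`), e.g. from [extract_impedances()].
#' @param cfg The [phantom_config()] providing theoretical values.
#' @return A tibble with `freq_hz` and percent columns `eps_in`,
#'   `eps_body`, `eps_out`, `eps_z`.
#' @examples
#' ph <- solve_node_phasors(phantom_config(), c(0.01, 1, 100))
#' spec <- extract_impedances(ph, r_ref = 100)
#' relative_errors(spec, phantom_config())
#' @export
relative_errors <- function(measured, cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  cols <- c("Zin", "Zbody", "Zout", "Z")
  stopifnot(all(c("freq_hz", cols) %in% names(measured)))
  theo <- phantom_impedances(cfg, measured$freq_hz)
  if (any(vapply(cols, function(cc) any(Mod(theo[[cc]]) == 0), logical(1))))
    abort("Theoretical impedance magnitude is zero; cannot form a relative error.")
  tibble(
    freq_hz = measured$freq_hz,
    eps_in = 100 * Mod(measured$Zin - theo$Zin) / Mod(theo$Zin),
    eps_body = 100 * Mod(measured$Zbody - theo$Zbody) / Mod(theo$Zbody),
    eps_out = 100 * Mod(measured$Zout - theo$Zout) / Mod(theo$Zout),
    eps_z = 100 * Mod(measured$Z - theo$Z) / Mod(theo$Z))
}

#' Maximum relative errors over a sweep
#'
#' @param errors A tibble from [relative_errors()].
#' @return A one-row tibble with the maxima of each error column (percent).
#' @export
max_relative_errors <- function(errors) {
  dplyr::summarise(errors, dplyr::across(dplyr::starts_with("eps_"), max))
}

#' Relative errors of extracted Cole--Cole parameters
#'
#' \eqn{\epsilon_x = 100\,|x' - x| / x} (percent) for each of `a`, `tau`,
#' `R0`, `Rinf` against their theoretical counterparts.
#'
#' @param fit A converged `cole_cole_fit` or a [cole_cole_params()] of
#'   extracted values.
#' @param truth The theoretical [cole_cole_params()].
#' @return A tibble with columns `term`, `estimate`, `truth`, `error_pct`.
#' @examples
#' est <- cole_cole_params(R0 = 11107, Rinf = 996.31, tau = 0.1017, a = 0.9687)
#' truth <- cole_cole_params(R0 = 11e3, Rinf = 1e3, tau = 0.1, a = 1)
#' parameter_errors(est, truth)
#' @export
parameter_errors <- function(fit, truth) {
  stopifnot(inherits(truth, "cole_cole_params"))
  est <- if (inherits(fit, "cole_cole_fit")) {
    if (!fit$converged) abort("Fit did not converge; no parameters to compare.")
    fit$params
  } else if (inherits(fit, "cole_cole_params")) {
    fit
  } else {
    abort("`fit` must be a cole_cole_fit or cole_cole_params.")
  }
  terms <- c("a", "tau", "R0", "Rinf")
  est_v <- unlist(est[terms])
  tru_v <- unlist(truth[terms])
  tibble(term = terms, estimate = unname(est_v), truth = unname(tru_v),
         error_pct = unname(100 * abs(est_v - tru_v) / tru_v))
}

#' Average extracted Cole--Cole parameters over repeated fits
#'
#' Arithmetic mean of each parameter over converged fits, the summary used
#' to compare repeated recordings of the same phantom.
#'
#' @param fits A list of `cole_cole_fit` objects, or a data frame with
#'   columns `a`, `tau`, `R0`, `Rinf` (and optionally `converged`).
#' @return A one-row tibble with mean `a`, `tau`, `R0`, `Rinf` and the
#'   count `n_fits` averaged.
#' @examples
#' summarize_parameters(
#'   data.frame(a = c(0.9687, 0.9867, 0.9796, 0.9845, 0.9833),
#'              tau = 0.1, R0 = 11e3, Rinf = 1e3))
#' @export
summarize_parameters <- function(fits) {
  if (is.data.frame(fits)) {
    df <- as_tibble(fits)
    if ("converged" %in% names(df)) df <- df[df$converged, ]
  } else {
    fits <- Filter(function(f) inherits(f, "cole_cole_fit") && f$converged,
                   fits)
    df <- purrr::map_dfr(fits, function(f) as_tibble(as.list(coef(f))))
  }
  if (nrow(df) == 0) abort("No converged fits to summarize.")
  stopifnot(all(c("a", "tau", "R0", "Rinf") %in% names(df)))
  tibble(a = mean(df$a), tau = mean(df$tau), R0 = mean(df$R0),
         Rinf = mean(df$Rinf), n_fits = nrow(df))
}
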