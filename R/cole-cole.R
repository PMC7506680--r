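#' Cole--Cole relaxation parameters
#'
#' Bundle of the four parameters of the Cole--Cole dispersion model
#' \deqn{Z(j\omega) = R_\infty + \frac{R_0 - R_\infty}{1 + (j\omega\tau)^a},}
#' the standard single-dispersion description of dielectric relaxation in
#' tissue. `a = 1` reduces to the Debye model (an ideal capacitor in the
#' relaxation branch); `a < 1` corresponds to a constant-phase element.
#'
#' @param R0 Resistance at zero frequency, in ohms. Must exceed `Rinf`.
#' @param Rinf Resistance at infinite frequency, in ohms. Must be positive.
#' @param tau Relaxation time constant, in seconds. Must be positive.
#' @param a Dispersion exponent, dimensionless, in (0, 1].
#'
#' @return An object of class `cole_cole_params` (a named list).
#' @examples
#' cole_cole_params(R0 = 11e3, Rinf = 1e3, tau = 0.1, a = 1)
#' @export
cole_cole_params <- function(R0, Rinf, tau, a = 1) {
  stopifnot(is.numeric(R0), is.numeric(Rinf), is.numeric(tau), is.numeric(a))
  if (!is.finite(R0) || !is.finite(Rinf) || !is.finite(tau) || !is.finite(a))
    abort("Cole-Cole parameters must all be finite.")
  if (Rinf <= 0) abort("`Rinf` must be positive.")
  if (R0 <= Rinf) abort("`R0` must exceed `Rinf`.")
  if (tau <= 0) abort("`tau` must be positive.")
  if (a <= 0 || a > 1) abort("`a` must lie in (0, 1].")
  structure(list(R0 = R0, Rinf = Rinf, tau = tau, a = a),
            class = "cole_cole_params")
}

#' @export
print.cole_cole_params <- function(x, ...) {
  cat("<cole_cole_params>\n")
  cat(sprintf("  R0   = %g Ohm\n  Rinf = %g Ohm\n  tau  = %g s\n  a    = %g\n",
              x$R0, x$Rinf, x$tau, x$a))
  invisible(x)
}

#' Complex impedance of the Cole--Cole model
#'
#' Evaluates \eqn{Z(j\omega) = R_\infty + (R_0-R_\infty)/(1+(j\omega\tau)^a)}
#' with \eqn{\omega = 2\pi f}. The principal branch is used for the complex
#' power, the standard Cole--Cole convention, so the impedance is continuous
#' in `a` at the Debye limit `a = 1`. Time convention is
#' \eqn{e^{+j\omega t}}: capacitive reactance has a negative imaginary part.
#'
#' @param params A [cole_cole_params()] object.
#' @param freq Frequency in Hz (ordinary frequency, not angular). Vectorised;
#'   all values must be finite and non-negative.
#'
#' @return Complex vector of impedances, in ohms, one per frequency.
#' @examples
#' p <- cole_cole_params(R0 = 11e3, Rinf = 1e3, tau = 0.1, a = 1)
#' cole_cole_impedance(p, 0)                  # 11 kOhm at DC
#' cole_cole_impedance(p, 10 / (2 * pi))      # omega * tau = 1
#' @export
cole_cole_impedance <- function(params, freq) {
  stopifnot(inherits(params, "cole_cole_params"))
  check_freq(freq)
  w <- 2 * pi * freq
  params$Rinf + (params$R0 - params$Rinf) /
    (1 + (1i * w * params$tau)^params$a)
}

check_freq <- function(freq, positive = FALSE) {
  if (!is.numeric(freq) || any(!is.finite(freq)))
    abort("`freq` must be finite and numeric.")
  if (positive) {
    if (any(freq <= 0)) abort("`freq` must be positive.")
  } else if (any(freq < 0)) {
    abort("`freq` must be non-negative.")
  }
  invisible(freq)
}
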