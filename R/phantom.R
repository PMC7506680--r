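#' Parallel RC element
#'
#' A resistor and capacitor in parallel, the lumped model used for the
#' electrode--sample contact ("residual") impedances at both ends of the
#' measurement chain.
#'
#' @param R Resistance in ohms, positive.
#' @param C Capacitance in farads, non-negative (`C = 0` is a bare resistor).
#' @return An object of class `parallel_rc`.
#' @examples
#' parallel_rc(R = 100e3, C = 100e-6)
#' @export
parallel_rc <- function(R, C = 0) {
  stopifnot(is.numeric(R), is.numeric(C))
  if (!is.finite(R) || R <= 0) abort("`R` must be positive and finite.")
  if (!is.finite(C) || C < 0) abort("`C` must be non-negative and finite.")
  structure(list(R = R, C = C), class = "parallel_rc")
}

#' @export
print.parallel_rc <- function(x, ...) {
  cat(sprintf("<parallel_rc> R = %g Ohm, C = %g F\n", x$R, x$C))
  invisible(x)
}

#' Impedance of a parallel RC element
#'
#' \eqn{Z = 1 / (1/R + j\omega C)} with \eqn{\omega = 2\pi f}. At DC the
#' capacitor is open and the impedance equals `R`.
#'
#' @param rc A [parallel_rc()] element.
#' @param freq Frequency in Hz; vectorised, non-negative.
#' @return Complex impedance vector, ohms.
#' @export
parallel_rc_impedance <- function(rc, freq) {
  stopifnot(inherits(rc, "parallel_rc"))
  check_freq(freq)
  1 / (1 / rc$R + 1i * 2 * pi * freq * rc$C)
}

#' Validation phantom configuration
#'
#' Describes the series four-node phantom circuit used to validate the
#' measurement chain: a contact impedance `contact_in`, a Debye "body"
#' branch (`body_Rinf` in series with `body_dR` parallel to `body_C`), a
#' contact impedance `contact_out`, and a reference resistor `Rref` to
#' ground. Component tolerances are stored for Monte-Carlo perturbation but
#' are not applied unless a perturbed copy is requested explicitly (see
#' [perturb_phantom()]); theoretical spectra always use nominal values.
#'
#' The default arguments are the nominal components of the physical
#' validation phantom: 100 kOhm / 100 uF contacts, a 1 kOhm + (10 kOhm ||
#' 10 uF) body giving R0 = 11 kOhm and tau = 0.1 s, and Rref = 100 Ohm,
#' with 1% resistor and 5% capacitor tolerances.
#'
#' @param contact_in,contact_out [parallel_rc()] contact impedances.
#' @param body_Rinf Series body resistance (high-frequency limit), ohms.
#' @param body_dR Relaxation-branch resistance `R0 - Rinf`, ohms.
#' @param body_C Relaxation-branch capacitance, farads.
#' @param Rref Reference resistor, ohms.
#' @param r_tolerance,c_tolerance Fractional component tolerances in
#'   \[0, 0.2\], used only by [perturb_phantom()].
#' @return An object of class `phantom_config`.
#' @examples
#' phantom_config()  # the nominal validation phantom
#' @export
phantom_config <- function(contact_in = parallel_rc(100e3, 100e-6),
                           contact_out = parallel_rc(100e3, 100e-6),
                           body_Rinf = 1e3,
                           body_dR = 10e3,
                           body_C = 10e-6,
                           Rref = 100,
                           r_tolerance = 0.01,
                           c_tolerance = 0.05) {
  stopifnot(inherits(contact_in, "parallel_rc"),
            inherits(contact_out, "parallel_rc"))
  for (v in c(body_Rinf = body_Rinf, body_dR = body_dR, Rref = Rref))
    if (!is.finite(v) || v <= 0) abort("All resistances must be positive.")
  if (!is.finite(body_C) || body_C < 0) abort("`body_C` must be non-negative.")
  for (tol in c(r_tolerance, c_tolerance))
    if (!is.finite(tol) || tol < 0 || tol > 0.2)
      abort("Tolerances must lie in [0, 0.2].")
  structure(list(contact_in = contact_in, contact_out = contact_out,
                 body_Rinf = body_Rinf, body_dR = body_dR, body_C = body_C,
                 Rref = Rref,
                 r_tolerance = r_tolerance, c_tolerance = c_tolerance),
            class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config>\n")
  cat(sprintf("  contact_in : R = %g Ohm, C = %g F\n",
              x$contact_in$R, x$contact_in$C))
  cat(sprintf("  body       : Rinf = %g Ohm, dR = %g Ohm, C = %g F\n",
              x$body_Rinf, x$body_dR, x$body_C))
  cat(sprintf("  contact_out: R = %g Ohm, C = %g F\n",
              x$contact_out$R, x$contact_out$C))
  cat(sprintf("  Rref = %g Ohm; tolerances R %g%%, C %g%%\n",
              x$Rref, 100 * x$r_tolerance, 100 * x$c_tolerance))
  invisible(x)
}

#' Cole--Cole parameters implied by a phantom body branch
#'
#' The Debye body branch of the phantom is the `a = 1` special case of the
#' Cole--Cole model with `R0 = body_Rinf + body_dR` and
#' `tau = body_dR * body_C`.
#'
#' @param cfg A [phantom_config()].
#' @return A [cole_cole_params()] object with `a = 1`.
#' @export
phantom_body_params <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  cole_cole_params(R0 = cfg$body_Rinf + cfg$body_dR, Rinf = cfg$body_Rinf,
                   tau = theoretical_tau(cfg), a = 1)
}

#' Theoretical relaxation time constant of the phantom
#'
#' For the Debye body branch the time constant is the product of the
#' relaxation-branch resistance and capacitance,
#' \eqn{\tau = (R_0 - R_\infty) \cdot C}.
#'
#' @param cfg A [phantom_config()].
#' @return Time constant in seconds.
#' @examples
#' theoretical_tau(phantom_config())  # 0.1 s for the nominal phantom
#' @export
theoretical_tau <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  cfg$body_dR * cfg$body_C
}

#' Theoretical impedances of the phantom circuit
#'
#' Closed-form complex impedances of the three series blocks and their sum:
#' `Zin` and `Zout` are the parallel-RC contacts, `Zbody` is the Debye body
#' branch, and `Z = Zin + Zbody + Zout` is the resultant ("two-electrode")
#' impedance.
#'
#' @param cfg A [phantom_config()].
#' @param freq Frequencies in Hz; vectorised, non-negative.
#' @return A tibble with columns `freq_hz` and complex columns `Zin`,
#'   `Zbody`, `Zout`, `Z` (ohms).
#' @examples
#' phantom_impedances(phantom_config(), c(0, 1, 100))
#' @export
phantom_impedances <- function(cfg, freq) {
  stopifnot(inherits(cfg, "phantom_config"))
  check_freq(freq)
  Zin <- parallel_rc_impedance(cfg$contact_in, freq)
  Zbody <- cole_cole_impedance(phantom_body_params(cfg), freq)
  Zout <- parallel_rc_impedance(cfg$contact_out, freq)
  tibble(freq_hz = freq, Zin = Zin, Zbody = Zbody, Zout = Zout,
         Z = Zin + Zbody + Zout)
}

#' Exact node phasors of the series measurement loop
#'
#' Solves the series loop generator -> node 1 -> Zin -> node 2 -> Zbody ->
#' node 3 -> Zout -> node 4 -> Rref -> ground exactly: the loop current is
#' `I = v_gen / (Zin + Zbody + Zout + Rref)` and the node voltages follow by
#' Ohm's law. These are the noise-free phasors an ideal four-channel
#' front end would measure, and applying the voltage-comparison extraction
#' formulas to them recovers the block impedances identically.
#'
#' Phasor convention: `u(t) = Re(u_hat * exp(j * 2 * pi * f * t))`.
#'
#' @param cfg A [phantom_config()].
#' @param freq Frequencies in Hz; vectorised, non-negative.
#' @param v_gen Generator peak amplitude in volts (phasor of node 1).
#' @return A tibble with columns `freq_hz` and complex columns `u1`..`u4`
#'   (volts, peak).
#' @examples
#' solve_node_phasors(phantom_config(), c(0.001, 1, 1000), v_gen = 0.5)
#' @export
solve_node_phasors <- function(cfg, freq, v_gen = 0.5) {
  stopifnot(inherits(cfg, "phantom_config"))
  check_freq(freq)
  if (!is.numeric(v_gen) || !is.finite(v_gen) || v_gen <= 0)
    abort("`v_gen` must be a positive peak voltage.")
  z <- phantom_impedances(cfg, freq)
  ztot <- z$Z + cfg$Rref
  if (any(Mod(ztot) == 0)) abort("Total loop impedance is zero.")
  I <- v_gen / ztot
  u1 <- rep(complex(real = v_gen), length(freq))
  u2 <- u1 - I * z$Zin
  u4 <- I * cfg$Rref
  u3 <- u4 + I * z$Zout
  tibble(freq_hz = freq, u1 = u1, u2 = u2, u3 = u3, u4 = u4)
}

#' Draw a component-tolerance-perturbed copy of a phantom
#'
#' Each resistance is multiplied by `1 + delta` with `delta` uniform in
#' `+/- r_tolerance` and each capacitance by an independent uniform factor
#' in `+/- c_tolerance`, emulating the spread of commercial components.
#' Deterministic given `seed`.
#'
#' @param cfg A [phantom_config()].
#' @param seed Integer seed for the draw.
#' @return A new `phantom_config` with perturbed component values (and the
#'   same tolerance fields).
#' @export
perturb_phantom <- function(cfg, seed) {
  stopifnot(inherits(cfg, "phantom_config"))
  local_seed(seed)
  jr <- function(x) x * (1 + stats::runif(1, -cfg$r_tolerance, cfg$r_tolerance))
  jc <- function(x) x * (1 + stats::runif(1, -cfg$c_tolerance, cfg$c_tolerance))
  phantom_config(
    contact_in = parallel_rc(jr(cfg$contact_in$R), jc(cfg$contact_in$C)),
    contact_out = parallel_rc(jr(cfg$contact_out$R), jc(cfg$contact_out$C)),
    body_Rinf = jr(cfg$body_Rinf),
    body_dR = jr(cfg$body_dR),
    body_C = jc(cfg$body_C),
    Rref = jr(cfg$Rref),
    r_tolerance = cfg$r_tolerance,
    c_tolerance = cfg$c_tolerance
  )
}

# Set the RNG seed for the calling frame only, restoring global state after.
local_seed <- function(seed, env = parent.frame()) {
  if (!is.numeric(seed) || !is.finite(seed))
    abort("`seed` must be a finite integer.")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  withr::defer(
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv()),
    envir = env)
  invisible(seed)
}
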