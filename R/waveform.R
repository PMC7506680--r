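#' Synthesize sampled four-channel node voltages
#'
#' Produces the time-domain signals an ideal four-channel ADC front end
#' would record at the phantom nodes under sinusoidal voltage excitation:
#' each channel is `Re(u_hat * exp(j*2*pi*f*t))` with `u_hat` the exact node
#' phasor from [solve_node_phasors()], sampled at `fs` for a whole number of
#' excitation periods, plus the imperfections described by a
#' [noise_model()]. The excitation starts at a rising zero crossing
#' (generator phase -90 degrees), the start condition the sweep generator
#' uses when stepping frequency.
#'
#' @param cfg A [phantom_config()].
#' @param f_exc Excitation frequency, Hz (positive).
#' @param v_gen Generator peak amplitude, volts (0.5 V peak = 1 V
#'   peak-to-peak, the validation protocol's level).
#' @param fs Sampling rate, samples/s; must exceed `2 * f_exc`. Default
#'   picks the fast-profile rate for `f_exc` (see [select_sampling_rate()]).
#' @param n_periods Number of excitation periods to synthesize (>= 1).
#' @param noise A [noise_model()]; default [noise_off()].
#' @param start `"zero"` (rising zero crossing, default) or `"max"`
#'   (cosine maximum) excitation start.
#' @return A `waveform_block`: a tibble with columns `t` (s) and `u1`..`u4`
#'   (V), carrying `fs`, `f_exc`, `v_gen` and the exact node phasors as
#'   attributes.
#' @examples
#' wf <- synthesize_waveforms(phantom_config(), f_exc = 10, n_periods = 4)
#' head(wf)
#' @export
synthesize_waveforms <- function(cfg, f_exc, v_gen = 0.5, fs = NULL,
                                 n_periods = 8, noise = noise_off(),
                                 start = c("zero", "max")) {
  stopifnot(inherits(cfg, "phantom_config"), inherits(noise, "noise_model"))
  check_freq(f_exc, positive = TRUE)
  start <- match.arg(start)
  fs <- fs %||% select_sampling_rate(f_exc, "fast")
  if (fs <= 2 * f_exc)
    abort(sprintf("Nyquist violation: fs = %g must exceed 2 * f_exc = %g.",
                  fs, 2 * f_exc))
  if (n_periods < 1) abort("`n_periods` must be >= 1.")

  n <- round(n_periods * fs / f_exc)
  t <- (seq_len(n) - 1) / fs
  w <- 2 * pi * f_exc

  ph <- solve_node_phasors(cfg, f_exc, v_gen)
  rot <- if (start == "zero") exp(-1i * pi / 2) else 1 + 0i
  phasors <- c(u1 = ph$u1, u2 = ph$u2, u3 = ph$u3, u4 = ph$u4) * rot

  if (noise$white_rms > 0) local_seed(noise$seed)
  channels <- lapply(phasors, function(u) {
    x <- Re(u * exp(1i * w * t))
    for (h in noise$harmonic_levels) {
      if (h[1] * f_exc < fs / 2) {
        amp <- 10^(h[2] / 20) * Mod(u)
        x <- x + amp * cos(h[1] * (w * t + Arg(u)))
      }
    }
    x + channel_noise(n, noise$white_rms, noise$pink_fraction)
  })

  out <- tibble(t = t, u1 = channels$u1, u2 = channels$u2,
                u3 = channels$u3, u4 = channels$u4)
  structure(out, fs = fs, f_exc = f_exc, v_gen = v_gen,
            n_periods = n_periods, phasors = phasors,
            class = c("waveform_block", class(out)))
}

#' Metadata of a waveform block
#'
#' @param block A `waveform_block` from [synthesize_waveforms()].
#' @return A list with `fs`, `f_exc`, `v_gen`, `n_periods` and the exact
#'   node `phasors` used for synthesis.
#' @export
waveform_meta <- function(block) {
  stopifnot(inherits(block, "waveform_block"))
  list(fs = attr(block, "fs"), f_exc = attr(block, "f_exc"),
       v_gen = attr(block, "v_gen"), n_periods = attr(block, "n_periods"),
       phasors = attr(block, "phasors"))
}
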