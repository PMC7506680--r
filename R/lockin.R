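#' Lock-in reference configuration
#'
#' The internal reference oscillator of the phase-sensitive detector:
#' `Vr * cos(2*pi*fr*t - phi_r)` (and its quadrature). The reference
#' frequency must equal the excitation frequency of the block being
#' demodulated.
#'
#' @param fr Reference frequency, Hz (positive).
#' @param Vr Reference amplitude (dimensionless scale), positive; the
#'   demodulator output is normalized by it, so its value is immaterial.
#' @param phi_r Reference phase, radians.
#' @return An object of class `reference_config`.
#' @export
reference_config <- function(fr, Vr = 1, phi_r = 0) {
  check_freq(fr, positive = TRUE)
  if (!is.numeric(Vr) || Vr <= 0) abort("`Vr` must be positive.")
  structure(list(Vr = Vr, fr = fr, phi_r = phi_r),
            class = "reference_config")
}

#' Demodulation filter configuration
#'
#' Optional single- or two-pole RC low-pass applied to the mixer products
#' before whole-period averaging. With whole-period integration the filter
#' is mathematically redundant (the averaging itself removes the
#' double-frequency term), which is why the measurement protocol runs with
#' filters off; it is provided for studying filtered operation.
#'
#' @param lowpass_order 0 (off, default), 1 or 2.
#' @param lowpass_cutoff Cut-off frequency, Hz; required when order > 0.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(lowpass_order = 0, lowpass_cutoff = NULL) {
  if (!lowpass_order %in% 0:2) abort("`lowpass_order` must be 0, 1 or 2.")
  if (lowpass_order > 0 &&
      (is.null(lowpass_cutoff) || lowpass_cutoff <= 0))
    abort("A positive `lowpass_cutoff` is required when the filter is on.")
  structure(list(lowpass_order = lowpass_order,
                 lowpass_cutoff = lowpass_cutoff),
            class = "filter_config")
}

#' Digital lock-in demodulation of one channel
#'
#' Phase-sensitive detection: the sampled signal is multiplied by the
#' in-phase and quadrature references, optionally low-pass filtered, and
#' averaged over the largest whole number of reference periods that fits in
#' the block (leftover samples are discarded). For a signal
#' `Vs * cos(2*pi*f*t - phi_s)` the averages are
#' `0.5*Vs*Vr*cos(phi_r - phi_s)` and `0.5*Vs*Vr*sin(phi_r - phi_s)`, from
#' which amplitude and phase are recovered as
#' `Vs = (2/Vr)*sqrt(VX^2 + VY^2)` and `phi_s = phi_r + atan2(VY, VX)`.
#'
#' Whole periods are counted in time, not in samples, so non-integer
#' samples-per-period blocks are accepted (with an O(1/n) truncation
#' error).
#'
#' @param block A `waveform_block`, or a plain numeric vector of samples
#'   (then `fs` must be given).
#' @param channel Channel name `"u1"`..`"u4"` (or column index); ignored
#'   when `block` is a numeric vector.
#' @param ref A [reference_config()]; default: matched reference at the
#'   block's excitation frequency with `phi_r = 0`.
#' @param filt A [filter_config()]; default: filters off.
#' @param fs Sampling rate in Hz when `block` is a numeric vector.
#' @return A `lockin_phasor`: list with `amplitude` (V peak), `phase`
#'   (rad, in (-pi, pi], the phase lag phi_s of the cosine convention),
#'   `phasor` (complex, `amplitude * exp(-1i*phase)`), and `n_periods`
#'   integrated.
#' @examples
#' wf <- synthesize_waveforms(phantom_config(), f_exc = 100, n_periods = 16)
#' demodulate(wf, "u2")
#' @export
demodulate <- function(block, channel = "u1", ref = NULL,
                       filt = filter_config(), fs = NULL) {
  if (inherits(block, "waveform_block")) {
    fs <- attr(block, "fs")
    f_blk <- attr(block, "f_exc")
    x <- block[[channel]]
  } else {
    if (is.null(fs)) abort("`fs` is required for plain sample vectors.")
    f_blk <- NULL
    x <- as.numeric(block)
  }
  ref <- ref %||% reference_config(fr = f_blk)
  stopifnot(inherits(ref, "reference_config"), inherits(filt, "filter_config"))
  if (!is.null(f_blk) && abs(ref$fr - f_blk) > 1e-9 * f_blk)
    abort("Reference frequency must match the block excitation frequency.")
  f <- ref$fr
  n <- length(x)

  periods_avail <- n / fs * f
  n_per <- floor(periods_avail + 1e-9)
  if (n_per < 1)
    abort("Block holds fewer samples than one reference period.")
  m <- floor(n_per * fs / f + 1e-9)
  x <- x[seq_len(m)]
  t <- (seq_len(m) - 1) / fs

  arg <- 2 * pi * f * t - ref$phi_r
  VA <- x * ref$Vr * cos(arg)
  VB <- x * ref$Vr * sin(arg)
  if (filt$lowpass_order > 0) {
    VA <- apply_lowpass(VA, fs, filt$lowpass_order, filt$lowpass_cutoff)
    VB <- apply_lowpass(VB, fs, filt$lowpass_order, filt$lowpass_cutoff)
  }
  VX <- mean(VA)
  VY <- mean(VB)

  amplitude <- 2 / ref$Vr * sqrt(VX^2 + VY^2)
  # cos(wt - phi_s) * sin(wt - phi_r) averages to 0.5*sin(phi_s - phi_r),
  # so the recovered signal phase is phi_r + atan2(VY, VX).
  phase <- wrap_phase(ref$phi_r + atan2(VY, VX))
  structure(list(amplitude = amplitude, phase = phase,
                 phasor = amplitude * exp(-1i * phase),
                 n_periods = n_per),
            class = "lockin_phasor")
}

#' @export
print.lockin_phasor <- function(x, ...) {
  cat(sprintf("<lockin_phasor> amplitude = %.9g V, phase = %.9g rad (%d periods)\n",
              x$amplitude, x$phase, x$n_periods))
  invisible(x)
}

# Wrap an angle into (-pi, pi].
wrap_phase <- function(x) {
  -(((-x + pi) %% (2 * pi)) - pi)
}

#' Discrete single- or two-pole RC low-pass filter
#'
#' First-order section `y[k] = y[k-1] + alpha * (x[k] - y[k-1])` with
#' `alpha = dt / (RC + dt)`, `RC = 1/(2*pi*cutoff)`; order 2 cascades two
#' identical sections. DC gain is exactly 1. The filter state is
#' initialized at the mean of the input, which suppresses the start-up
#' transient that a zero-initialized one-pole filter would superimpose on a
#' finite observation window.
#'
#' @param series Numeric sample vector.
#' @param fs Sampling rate, Hz.
#' @param order 1 or 2.
#' @param cutoff -3 dB corner frequency, Hz, in (0, fs/2).
#' @param init Initial state: `"mean"` (default), `"first"` sample, or
#'   `"zero"`.
#' @return Filtered numeric vector of the same length.
#' @export
apply_lowpass <- function(series, fs, order = 1, cutoff, init = "mean") {
  if (!order %in% 1:2) abort("`order` must be 1 or 2.")
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= fs / 2)
    abort("`cutoff` must lie in (0, fs/2).")
  dt <- 1 / fs
  rc <- 1 / (2 * pi * cutoff)
  alpha <- dt / (rc + dt)
  y0 <- switch(init,
               mean = mean(series),
               first = series[1],
               zero = 0,
               abort('`init` must be "mean", "first" or "zero".'))
  out <- series
  for (i in seq_len(order)) {
    out <- as.numeric(stats::filter(alpha * out, 1 - alpha,
                                    method = "recursive", init = y0))
  }
  out
}

#' Single-sided FFT amplitude spectrum
#'
#' Amplitude spectrum of one channel, normalized so a full-scale sinusoid
#' centred on a bin reads its peak amplitude (0 dB for 1 V peak). An
#' optional Hann window (with coherent-gain correction) reduces leakage for
#' non-bin-centred tones.
#'
#' @param block A `waveform_block` or numeric sample vector.
#' @param channel Channel name/index when `block` is a waveform block.
#' @param window `"none"` (default) or `"hann"`.
#' @param fs Sampling rate when `block` is a numeric vector.
#' @return A tibble with `freq_hz`, `amplitude_v` (peak volts) and
#'   `level_db` (dB re 1 V peak).
#' @examples
#' wf <- synthesize_waveforms(phantom_config(), f_exc = 0.8, n_periods = 8)
#' spec <- fft_spectrum(wf, "u2")
#' spec[which.max(spec$amplitude_v), ]
#' @export
fft_spectrum <- function(block, channel = "u2", window = c("none", "hann"),
                         fs = NULL) {
  window <- match.arg(window)
  if (inherits(block, "waveform_block")) {
    fs <- attr(block, "fs")
    x <- block[[channel]]
  } else {
    if (is.null(fs)) abort("`fs` is required for plain sample vectors.")
    x <- as.numeric(block)
  }
  n <- length(x)
  if (n < 2) abort("At least two samples are required.")
  w <- switch(window,
              none = rep(1, n),
              hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n))
  X <- fft(x * w)
  half <- floor(n / 2) + 1
  amp <- 2 * Mod(X[seq_len(half)]) / sum(w)
  amp[1] <- amp[1] / 2  # DC bin is not doubled
  tibble(freq_hz = (seq_len(half) - 1) * fs / n,
         amplitude_v = amp,
         level_db = 20 * log10(pmax(amp, .Machine$double.xmin)))
}
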