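#' Select the sampling rate for an excitation frequency
#'
#' The `"paper"` profile reproduces the instrument's fixed rates: 375
#' ksample/s above 10 kHz, 37.5 ksample/s from 1 mHz to 10 kHz. The
#' `"fast"` profile is a simulation-friendly rule that caps the work per
#' point: the samples-per-period count is the instrument rate's, clamped to
#' \[16, 2000\] and rounded to an integer, and the rate is `spp * f`.
#' Rounding to integer samples per period makes whole-period sums exact, so
#' the fast profile trades none of the lock-in's accuracy for its speed.
#'
#' @param f Excitation frequency, Hz (positive; vectorised).
#' @param profile `"fast"` (default) or `"paper"`.
#' @return Sampling rate(s) in samples/s.
#' @examples
#' select_sampling_rate(50e3, "paper")  # 375000
#' select_sampling_rate(0.001, "fast")  # 2 samples/s (2000 per period)
#' @export
select_sampling_rate <- function(f, profile = c("fast", "paper")) {
  profile <- match.arg(profile)
  check_freq(f, positive = TRUE)
  fs_paper <- ifelse(f > 1e4, 375e3, 37.5e3)
  if (profile == "paper") return(fs_paper)
  spp <- pmin(2000, pmax(16, round(fs_paper / f)))
  spp * f
}

#' Integration length (whole periods) per sweep point
#'
#' The `"paper"` profile reproduces the instrument's empirically chosen
#' per-decade dwell times (33 s per decade from 10 Hz to 100 kHz, then 40,
#' 180, 1800 and about 18000 s for each successively lower decade down to
#' 1 mHz, as totals at 33 points per decade). The per-point duration is the
#' decade duration divided by `points_per_decade`, rounded to whole periods
#' (minimum 1). The `"fast"` profile uses a fixed number of periods per
#' point.
#'
#' @param f Excitation frequency, Hz (positive; vectorised).
#' @param profile `"fast"` (default) or `"paper"`.
#' @param points_per_decade Grid density used to apportion the paper
#'   profile's per-decade dwell times.
#' @param periods_fast Periods per point for the fast profile (default 8).
#' @return Integer count of whole excitation periods.
#' @export
integration_periods <- function(f, profile = c("fast", "paper"),
                                points_per_decade = 33, periods_fast = 8) {
  profile <- match.arg(profile)
  check_freq(f, positive = TRUE)
  if (profile == "fast") return(rep(as.integer(periods_fast), length(f)))
  decade_s <- ifelse(f >= 10, 33,
              ifelse(f >= 1, 40,
              ifelse(f >= 0.1, 180,
              ifelse(f >= 0.01, 1800, 18000))))
  pmax(1L, as.integer(round(decade_s / points_per_decade * f)))
}

#' Plan a log-equidistant frequency sweep
#'
#' Frequencies are placed equidistantly on the logarithmic scale,
#' `points_per_decade` per decade, from `f_min` up to (but excluding)
#' `f_max`, so a full-decade span of D decades yields exactly
#' `D * points_per_decade` points (e.g. 40 points for 5/decade over
#' 1 mHz--100 kHz). Each point carries its sampling rate and whole-period
#' integration length for the chosen profile.
#'
#' @param f_min,f_max Sweep limits in Hz, `0 < f_min < f_max`.
#' @param points_per_decade Number of frequencies per decade, in \[3, 100\].
#' @param profile `"fast"` (default) or `"paper"`; see
#'   [select_sampling_rate()] and [integration_periods()].
#' @param periods_fast Periods per point for the fast profile.
#' @return A `sweep_plan`: a tibble with columns `freq_hz`, `fs_hz`,
#'   `n_periods`, carrying the plan parameters as attributes.
#' @examples
#' plan_sweep(1e-3, 1e5, points_per_decade = 5)   # the 40-point protocol
#' @export
plan_sweep <- function(f_min, f_max, points_per_decade = 5,
                       profile = c("fast", "paper"), periods_fast = 8) {
  profile <- match.arg(profile)
  if (!is.numeric(f_min) || !is.numeric(f_max) || f_min <= 0 ||
      f_min >= f_max)
    abort("Require 0 < f_min < f_max.")
  if (points_per_decade < 3 || points_per_decade > 100)
    abort("`points_per_decade` must lie in [3, 100].")
  n_pts <- floor(points_per_decade * log10(f_max / f_min) + 1e-9)
  freqs <- f_min * 10^((seq_len(n_pts) - 1) / points_per_decade)
  out <- tibble(
    freq_hz = freqs,
    fs_hz = select_sampling_rate(freqs, profile),
    n_periods = integration_periods(freqs, profile, points_per_decade,
                                    periods_fast))
  structure(out, f_min = f_min, f_max = f_max,
            points_per_decade = points_per_decade, profile = profile,
            class = c("sweep_plan", class(out)))
}

#' Execute a frequency sweep through the virtual measurement chain
#'
#' For every planned frequency: synthesize the four node-voltage channels,
#' demodulate each against the generator reference (filters off), and
#' collect the resulting phasors. Noise is drawn from per-point sub-seeds
#' (`noise$seed + k - 1` with `k` the point's rank in frequency), so
#' results are reproducible and independent of execution order.
#'
#' @param cfg A [phantom_config()].
#' @param plan A [plan_sweep()] result.
#' @param v_gen Generator peak amplitude, volts (default 0.5 V peak =
#'   1 V peak-to-peak).
#' @param noise A [noise_model()]; default noiseless.
#' @return A tibble with one row per frequency x channel: `freq_hz`,
#'   `channel` (`"u1"`..`"u4"`), `amplitude_v`, `phase_rad` and complex
#'   `phasor`.
#' @examples
#' plan <- plan_sweep(0.01, 10, points_per_decade = 3)
#' run_sweep(phantom_config(), plan)
#' @export
run_sweep <- function(cfg, plan, v_gen = 0.5, noise = noise_off()) {
  stopifnot(inherits(cfg, "phantom_config"), inherits(plan, "sweep_plan"),
            inherits(noise, "noise_model"))
  # Sub-seeds are keyed to the point's rank in frequency, not its row
  # position, so executing the points in any order gives identical results.
  purrr::pmap_dfr(
    list(plan$freq_hz, plan$fs_hz, plan$n_periods,
         rank(plan$freq_hz, ties.method = "first")),
    function(f, fs, n_per, k) {
      pt_noise <- noise
      if (!is.null(noise$seed)) pt_noise$seed <- noise$seed + k - 1
      wf <- tryCatch(
        synthesize_waveforms(cfg, f_exc = f, v_gen = v_gen, fs = fs,
                             n_periods = n_per, noise = pt_noise),
        error = function(e) abort(sprintf(
          "Synthesis failed at %g Hz: %s", f, conditionMessage(e))))
      purrr::map_dfr(c("u1", "u2", "u3", "u4"), function(ch) {
        d <- tryCatch(
          demodulate(wf, ch),
          error = function(e) abort(sprintf(
            "Demodulation failed at %g Hz (%s): %s", f, ch,
            conditionMessage(e))))
        tibble(freq_hz = f, channel = ch, amplitude_v = d$amplitude,
               phase_rad = d$phase, phasor = d$phasor)
      })
    })
}

#' Pivot a long phasor table to one row per frequency
#'
#' @param phasors A long phasor table as returned by [run_sweep()].
#' @return A tibble with columns `freq_hz` and complex `u1`..`u4`.
#' @export
phasors_wide <- function(phasors) {
  stopifnot(all(c("freq_hz", "channel", "phasor") %in% names(phasors)))
  tidyr::pivot_wider(phasors[c("freq_hz", "channel", "phasor")],
                     names_from = "channel", values_from = "phasor")
}
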