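---
title: "A virtual four-electrode bio-impedance measurement chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual four-electrode bio-impedance measurement chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(lockinbis)
```

## The measurement problem

Electrical impedance spectroscopy of biological material at ultra-low
frequencies (down to millihertz, where the alpha dispersion of tissue
lives) is dominated by *residual impedances*: the electrode--sample
contact impedances in series with the object of interest. In a
two-electrode measurement they add directly to the measured impedance; at
frequencies approaching DC they can exceed the body impedance by orders of
magnitude. The four-electrode, voltage-comparison technique modelled here
rejects them by construction. A voltage generator drives a series loop

```
generator -> node 1 -> Zin -> node 2 -> Zbody -> node 3 -> Zout -> node 4 -> Rref -> ground
```

and the potentials `u1..u4` at the four nodes are each measured against
ground. Every block impedance follows from ratios against the reference
resistor, e.g.

$$Z_{body}' = R_{ref}\,\frac{u_2-u_3}{u_4},$$

and because the same loop current flows everywhere, `Zin` and `Zout`
cancel exactly from `Zbody'`. The package implements this chain as a
*virtual instrument*: a closed-form phantom circuit, a sampled-waveform
front end with configurable imperfections, a digital lock-in amplifier,
the extraction formulas, and Cole--Cole parameter extraction with the
associated error metrics.

## The phantom and its models

The validation phantom is a passive circuit producing a life-like
ultra-low-frequency spectrum: parallel-RC contacts
(`Rin = Rout = 100 kOhm`, `Cin = Cout = 100 uF`), a Debye body branch
(`Rinf = 1 kOhm` in series with `dR = 10 kOhm` parallel to `C = 10 uF`),
and `Rref = 100 Ohm`. Its body branch is the `a = 1` case of the
Cole--Cole dispersion

$$Z(j\omega) = R_\infty + \frac{R_0-R_\infty}{1+(j\omega\tau)^a},$$

with theoretical values `R0 = 11 kOhm`, `tau = dR * C = 0.1 s`, `a = 1`.
Component tolerances (1% resistors, 5% capacitors) are stored in the
configuration and applied only by `perturb_phantom()`; theoretical
reference spectra always use nominal values.

Conventions, fixed once and used everywhere: time dependence
`exp(+j*w*t)` (capacitive reactance negative imaginary), frequencies in
ordinary hertz at every interface, the principal branch for
`(j*w*tau)^a` (continuous in `a` at the Debye limit), and phasors
`u_hat` defined so that `Re(u_hat * exp(j*w*t))` reproduces the signal —
a signal `V*cos(w*t - phi)` has phasor `V*exp(-1i*phi)`.

## Waveform synthesis

`synthesize_waveforms()` samples each channel from its exact node phasor
for a whole number of excitation periods, starting at a rising zero
crossing (the start condition the sweep generator uses when stepping
frequency; the alternative maximum-point start is available via
`start = "max"`). The noise model adds, per channel and independently:

* white Gaussian noise of RMS `white_rms` (default `3.2e-5` V — chosen so
  the FFT characterization run at 0.8 Hz with 16 000 samples shows a
  noise floor near -120 dB relative to the 1 V peak-to-peak carrier, the
  floor of the physical instrument; the instrument's input-referred
  densities are far below its load noise, so the total is a free model
  parameter);
* optionally a 1/f-shaped fraction of that RMS, generated by a truncated
  fractional-integration filter (-10 dB/decade), since only the shape
  matters for studying the lock-in's noise rejection;
* generator harmonics at configurable orders and dB levels (default: a
  third harmonic at -100 dB, matching the generator's THD+N class).
  Harmonics are scaled to each channel's own carrier rather than
  propagated through the circuit at the harmonic frequency — with
  whole-period integration they are orthogonal to the fundamental either
  way, which the test suite verifies.

ADC quantization and inter-channel cross-talk are deliberately not
modelled (32-bit converters make the former negligible at this scale).

## The digital lock-in

`demodulate()` multiplies the signal by in-phase and quadrature
references, optionally applies a discrete one- or two-pole RC low-pass,
and averages over the largest whole number of reference periods that fit;
trailing fractional-period samples are discarded. Whole periods are
counted *in time*, not in samples, so non-integer samples-per-period
blocks are accepted with an O(1/n) truncation error. For
`Vs*cos(w*t - phi_s)` the averages are `0.5*Vs*Vr*cos(phi_s - phi_r)` and
`0.5*Vs*Vr*sin(phi_s - phi_r)`, giving

$$V_s = \frac{2}{V_r}\sqrt{\bar V_X^2 + \bar V_Y^2},\qquad
  \varphi_s = \varphi_r + \operatorname{atan2}(\bar V_Y, \bar V_X).$$

Note the `+` sign: with the quadrature mixer `sin(w*t - phi_r)`, the
product-to-sum identity puts `sin(phi_s - phi_r)` in the DC term. Some
presentations print the opposite sign for this term; the closed-loop
tests (synthesize a known phase, demodulate, compare) pin the convention
used here.

With whole-period integration the low-pass is mathematically redundant —
the averaging annihilates the double-frequency term by itself — which is
why the filters default to off, and why the suite checks that filtered
and unfiltered paths agree to 0.1%. The discrete RC section
`y[k] = y[k-1] + alpha*(x[k] - y[k-1])`, `alpha = dt/(RC + dt)`, has
exactly unit DC gain; its state is initialized at the input mean so that
a finite observation window is not polluted by the start-up transient a
zero-initialized one-pole filter would add. `fft_spectrum()` provides the
spectral measurement mode, normalized so a bin-centred sinusoid reads its
peak amplitude (0 dB for 1 V peak), with Hann-window coherent-gain
correction when windowing is requested.

## Sweep profiles and problem sizes

`plan_sweep()` places frequencies log-equidistantly, `points_per_decade`
in [3, 100], over `[f_min, f_max)` — half-open by powers-of-ten
construction, which is what makes 5/10/33 points per decade over the
eight decades from 1 mHz to 100 kHz give exactly 40/80/264 points
(closing both endpoints would give `8N + 1`).

Two profiles fix per-point sampling and integration:

* **paper** — the physical instrument's settings: 375 kS/s above 10 kHz,
  37.5 kS/s below, and per-decade dwell times of 33 s/decade from 10 Hz
  to 100 kHz (the published 132 s figure for that four-decade span,
  split equally per decade) then 40, 180, 1800 and ~18 000 s for each
  successively lower decade, apportioned per point and rounded to whole
  periods. This is faithful but produces multi-megasample blocks at
  millihertz frequencies.
* **fast** — the simulation default: the samples-per-period count is the
  instrument's, clamped to [16, 2000] and **rounded to an integer**, with
  8 integration periods per point. Integer samples per period make the
  whole-period mixer sums exact geometric sums (they vanish to machine
  precision), so the fast profile loses none of the lock-in's accuracy;
  without the rounding, points where the instrument rate is a small
  non-integer multiple of the excitation frequency would carry
  percent-level truncation error from the fractional final sample. The
  worst case per point is 16 000 samples (2000 x 8), so a 40-point sweep
  across all four channels demodulates in about a second.

Both profiles satisfy Nyquist everywhere on any legal grid (verified as a
suite invariant). Per-point noise sub-seeds are `seed + rank(f) - 1`,
keyed to the point's rank in frequency rather than its row position, so
executing the plan in any order gives identical results; experiment
repeats use `seed + (r-1)*1e5`.

## Fitting and error metrics

`fit_cole_cole()` minimizes unweighted residuals stacked over real and
imaginary parts (the standard complex-NLLS reading; magnitude-only
fitting is available behind the `residuals` argument for sensitivity
analysis) with Levenberg--Marquardt. `Rinf`, `dR = R0 - Rinf` and `tau`
are optimized on the log scale, which enforces positivity and
`R0 > Rinf` without constraints; the exponent is box-bounded in (0, 1].
Box bounds were chosen over a logistic reparameterization because the
phantom truth sits exactly at the `a = 1` boundary, which a logistic map
can only approach asymptotically. Initialization is data-driven:
`Rinf` from `|Z|` at the highest frequency, `R0` from `|Z|` at the
lowest, `tau = 1/(2*pi*f*)` with `f*` the frequency of the largest
`|Im Z|`, `a = 0.9`. Degenerate (dispersion-free) spectra drive `dR`
toward zero and are reported as `converged = FALSE` rather than as an
error or a meaningless parameter set.

Goodness of fit is
`R^2 = 1 - sum(|Zhat_i - Z_i'|^2) / sum(|Zbar' - Z_i'|^2)` with the
complex mean `Zbar'` — equivalent to stacking real and imaginary parts —
and is invariant to a common real scale. Spectrum-level validation uses
`eps = 100*|Z' - Z|/|Z|` per channel and frequency; parameter-level
validation uses `eps_x = 100*|x' - x|/x` per Cole--Cole parameter. When
these are compared against published tables printed to two decimals,
errors are rounded to two decimals; several published cells are only
consistent with unrounded fitted parameters, so worked-example tests use
internally consistent cells only.

## What the simulation does and does not show

Passing tests demonstrate that the *evaluation method* is exact: with an
ideal front end, synthesis -> lock-in -> extraction reproduces the
phantom's block impedances to ~1e-12 relative, `Zbody'` is independent of
contact impedances varied over four orders of magnitude, and the fitted
parameters recover the truth. With white noise at the instrument's
-120 dB floor and only 8 integration periods per point, parameter errors
stay well inside the component tolerances (the suite's noisy-recovery
tests). What the simulation does **not** capture: parasitic coupling
between physical channels, electrode drift and polarization, generator
settling between frequency steps, temperature dependence of components,
and harmonic currents re-filtered by the circuit — the gap between the
~1e-13% noiseless simulation error and the ~3% error measured on the real
instrument is exactly the hardware error budget that the virtual chain
idealizes away.

## Worked example

```{r example, eval = FALSE}
cfg <- phantom_config()
plan <- plan_sweep(1e-3, 1e5, points_per_decade = 5)
ex <- run_experiment(cfg, plan, noise = noise_model(seed = 42),
                     repeats = 5, seed = 42)
ex$summary
summarize_parameters(ex$fits)
autoplot(ex$fit_averaged)
```
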