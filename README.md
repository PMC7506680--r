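# lockinbis

A virtual four-electrode bio-impedance spectroscopy (BIS) measurement
chain for the ultra-low frequency range (1 mHz – 100 kHz), written as a
tidyverse-style R package. It targets the regime where tissue
alpha-dispersion lives and where electrode–sample *residual impedances*
normally swamp the measurement: a voltage generator drives a series loop
through an input contact impedance `Zin`, the body under test `Zbody`, an
output contact `Zout` and a reference resistor `Rref`, and the four node
potentials `u1..u4` are measured against ground. Every block impedance is
then a ratio against the reference resistor,

    Zin'   = Rref (u1 - u2) / u4
    Zbody' = Rref (u2 - u3) / u4
    Zout'  = Rref (u3 / u4 - 1)
    Z'     = Rref (u1 / u4 - 1)

so the contact impedances cancel exactly from `Zbody'` — residual
rejection by construction rather than by off-line correction.

The package implements the whole chain as testable software:

* **Circuit models** — Cole–Cole dispersion
  `Z = Rinf + (R0 - Rinf) / (1 + (jωτ)^a)`, parallel-RC contacts, the
  nominal validation phantom (100 kΩ/100 µF contacts, 1 kΩ + 10 kΩ‖10 µF
  body, Rref = 100 Ω, hence R0 = 11 kΩ, τ = 0.1 s, a = 1), and the exact
  phasor solution of the series loop.
* **Signal synthesis** — sampled four-channel node voltages with
  configurable white/1-f channel noise, generator harmonics, and
  component-tolerance perturbation.
* **Digital lock-in** — phase-sensitive demodulation with whole-period
  integration, optional discrete RC low-pass sections, and an FFT
  spectral mode.
* **Sweep engine** — log-equidistant grids (5/decade over 8 decades = the
  40-point protocol), instrument-faithful or simulation-fast
  sampling/integration profiles.
* **Analysis** — relative-error spectra, Levenberg–Marquardt Cole–Cole
  fitting (`minpack.lm`) with `tidy()`/`glance()`/`autoplot()` methods,
  parameter relative errors, and complex-residual goodness of fit.

## Worked example

Five repeated 40-point sweeps of the nominal phantom with
instrument-level noise, averaged, fitted, and compared against theory:

```r
library(lockinbis)

cfg  <- phantom_config()                       # nominal validation phantom
plan <- plan_sweep(1e-3, 1e5, points_per_decade = 5)   # 40-point protocol
ex   <- run_experiment(cfg, plan, noise = noise_model(seed = 42),
                       repeats = 5, seed = 42)
ex
#> <bis_experiment> 5 repeats x 40 frequencies (fast profile)
#> Per-repeat fits:
#>  repeat_no r_squared a eps_a      tau  eps_tau    R0    eps_R0    Rinf  eps_Rinf
#>          1   0.99999 1     0 0.100028 0.028397 11003 0.0272951 1000.16 0.0161090
#>          2   1.00000 1     0 0.100009 0.008803 11001 0.0063895 1000.05 0.0045932
#>          3   1.00000 1     0 0.100021 0.020852 11002 0.0218435 1000.13 0.0125798
#>          4   1.00000 1     0 0.100035 0.035252 11003 0.0277701 1000.15 0.0154471
#>          5   1.00000 1     0 0.099959 0.040724 10998 0.0196963  999.84 0.0157593
#> max eps_body = 0.1954%, max eps_Z = 0.1952% (averaged spectrum)
```

Each row is one simulated recording: the goodness of fit `r_squared`, the
extracted Cole–Cole parameters and their percent errors against the
theoretical values (a = 1, τ = 0.1 s, R0 = 11 kΩ, Rinf = 1 kΩ). With
noise at the instrument's −120 dB floor, the resistances and time
constant are recovered to a few hundredths of a percent and the exponent
exactly, far inside the 1% resistor / 5% capacitor tolerances of the
phantom's components. The spectrum-level error `eps_body` grows toward
the lowest frequencies, where the reference-resistor voltage `u4` is
smallest relative to the channel noise.

```r
summarize_parameters(ex$fits)
#> # A tibble: 1 × 5
#>       a   tau     R0  Rinf n_fits
#>   <dbl> <dbl>  <dbl> <dbl>  <int>
#> 1     1 0.100 11001. 1000.      5

autoplot(ex$fit_averaged)   # Bode magnitude of data and fitted model
```

A thin command-line front end with `sweep`, `fftspec`, `fit`, `validate`
and `experiment` subcommands is installed at
`system.file("cli", "bis.R", package = "lockinbis")`.

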