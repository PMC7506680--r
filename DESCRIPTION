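Package: lockinbis
Title: Simulation and Analysis of Ultra-Low-Frequency Bio-Impedance
    Spectroscopy with Digital Lock-In Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A virtual four-electrode bio-impedance spectroscopy (BIS)
    measurement chain for the ultra-low frequency range (1 mHz - 100 kHz):
    closed-form impedance models of a tissue-mimicking phantom circuit
    (parallel-RC contact impedances around a Debye/Cole-Cole body branch),
    synthesis of sampled four-channel node voltages under sinusoidal
    excitation with configurable instrument noise and generator harmonics,
    digital lock-in (phase-sensitive) demodulation with whole-period
    integration, residual-impedance-rejecting impedance extraction by
    voltage comparison against a reference resistor, Cole-Cole parameter
    extraction by Levenberg-Marquardt regression, and the associated
    relative-error and goodness-of-fit validation metrics. All results are
    returned as tibbles so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
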