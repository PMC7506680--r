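# Shared fixtures and independent oracles for the test suite.

# Nominal validation phantom (100k/100uF contacts, 1k + 10k||10uF body,
# Rref 100 Ohm).
nominal_phantom <- function() phantom_config()

# Independent Debye-branch oracle: series resistance plus parallel RC,
# computed from the circuit formula rather than the Cole-Cole power form.
debye_branch_oracle <- function(Rinf, dR, C, f) {
  Rinf + 1 / (1 / dR + 1i * 2 * pi * f * C)
}

# Brute-force complex R^2: explicit loops over stacked real/imaginary
# residuals, independent of goodness_of_fit()'s vectorized path.
r_squared_bruteforce <- function(model, data) {
  zbar <- sum(data) / length(data)
  ss_res <- 0
  ss_tot <- 0
  for (i in seq_along(data)) {
    ss_res <- ss_res + (Re(model[i]) - Re(data[i]))^2 +
      (Im(model[i]) - Im(data[i]))^2
    ss_tot <- ss_tot + (Re(zbar) - Re(data[i]))^2 +
      (Im(zbar) - Im(data[i]))^2
  }
  1 - ss_res / ss_tot
}
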