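test_that("Cole-Cole impedance matches closed-form values at landmark frequencies", {
  p <- cole_cole_params(R0 = 11000, Rinf = 1000, tau = 0.1, a = 1)
  expect_equal(cole_cole_impedance(p, 0), 11000 + 0i)
  # omega * tau = 1: 1000 + 10000 / (1 + 1i)
  expect_equal(cole_cole_impedance(p, 10 / (2 * pi)), 6000 - 5000i,
               tolerance = 1e-12)
  expect_equal(Mod(cole_cole_impedance(p, 1e12)), 1000, tolerance = 1e-6)
})

test_that("Cole-Cole parameter invariants are enforced", {
  expect_error(cole_cole_params(1000, 11000, 0.1, 1), "R0")
  expect_error(cole_cole_params(11000, 1000, -1, 1), "tau")
  expect_error(cole_cole_params(11000, 1000, 0.1, 1.2), "a")
  expect_error(cole_cole_params(11000, 1000, 0.1, 0), "a")
  p <- cole_cole_params(11000, 1000, 0.1, 1)
  expect_error(cole_cole_impedance(p, -1), "freq")
  expect_error(cole_cole_impedance(p, NaN), "freq")
})

test_that("a = 1 reduces to the Debye branch circuit formula", {
  withr::with_seed(42, {
    for (i in 1:20) {
      rinf <- 10^runif(1, 1, 5)
      dr <- 10^runif(1, 2, 5)
      C <- 10^runif(1, -7, -4)
      f <- 10^runif(5, -3, 5)
      p <- cole_cole_params(R0 = rinf + dr, Rinf = rinf, tau = dr * C, a = 1)
      expect_equal(cole_cole_impedance(p, f),
                   debye_branch_oracle(rinf, dr, C, f),
                   tolerance = 1e-12)
    }
  })
})

test_that("Debye magnitude is non-increasing in frequency with correct limits", {
  p <- cole_cole_params(11000, 1000, 0.1, 1)
  f <- 10^seq(-4, 6, length.out = 200)
  m <- Mod(cole_cole_impedance(p, f))
  expect_true(all(diff(m) <= 1e-9))
  # within 0.1% of R0 / Rinf far below / above the dispersion
  expect_equal(Mod(cole_cole_impedance(p, 1 / (2 * pi * p$tau) / 1000)),
               p$R0, tolerance = 1e-3)
  expect_equal(Mod(cole_cole_impedance(p, 1000 / (2 * pi * p$tau))),
               p$Rinf, tolerance = 1e-3)
})

test_that("parallel RC impedance follows 1/(1/R + jwC)", {
  rc <- parallel_rc(100e3, 100e-6)
  expect_equal(parallel_rc_impedance(rc, 0), 100000 + 0i)
  # omega * R * C = 1: R / (1 + 1i)
  expect_equal(parallel_rc_impedance(rc, 0.1 / (2 * pi)), 50000 - 50000i,
               tolerance = 1e-12)
  expect_equal(parallel_rc_impedance(parallel_rc(100e3, 0), 12345),
               100000 + 0i)
})

test_that("phantom impedances give the documented DC values and symmetry", {
  cfg <- nominal_phantom()
  z0 <- phantom_impedances(cfg, 0)
  expect_equal(z0$Zbody, 11000 + 0i)
  expect_equal(z0$Z, 211000 + 0i)
  f <- 10^seq(-3, 5, length.out = 30)
  z <- phantom_impedances(cfg, f)
  expect_equal(z$Zin, z$Zout)          # identical contacts
  expect_equal(z$Z, z$Zin + z$Zbody + z$Zout)
})

test_that("theoretical time constant is the branch RC product", {
  expect_identical(theoretical_tau(nominal_phantom()), 0.1)
  expect_identical(theoretical_tau(phantom_config(body_dR = 1, body_C = 1)), 1)
  expect_identical(theoretical_tau(phantom_config(body_dR = 2000,
                                                  body_C = 5e-6)), 0.01)
})

test_that("node phasors solve the series loop exactly", {
  cfg <- nominal_phantom()
  # DC divider: I = 1 / 211100, u4 = 100 * I for 1 V excitation
  ph <- solve_node_phasors(cfg, 0, v_gen = 1)
  expect_equal(ph$u4, complex(real = 100 / 211100), tolerance = 1e-14)
  # algebraic identity: Rref * (u2 - u3) / u4 equals the body impedance
  f <- 10^seq(-3, 5, length.out = 25)
  ph <- solve_node_phasors(cfg, f)
  zb <- cfg$Rref * (ph$u2 - ph$u3) / ph$u4
  expect_equal(zb, phantom_impedances(cfg, f)$Zbody, tolerance = 1e-13)
  # vanishing contacts: u1 ~ u2 and u3 ~ u4
  tiny <- phantom_config(contact_in = parallel_rc(1e-9, 0),
                         contact_out = parallel_rc(1e-9, 0))
  pht <- solve_node_phasors(tiny, c(0.01, 1, 100))
  expect_equal(pht$u1, pht$u2, tolerance = 1e-9)
  expect_equal(pht$u3, pht$u4, tolerance = 1e-9)
})

test_that("extraction formulas applied to exact phasors recover the block impedances", {
  cfg <- nominal_phantom()
  f <- 10^seq(-3, 5, length.out = 41)
  ph <- solve_node_phasors(cfg, f)
  got <- extract_impedances(ph, r_ref = cfg$Rref)
  want <- phantom_impedances(cfg, f)
  # the body channel (the measurand) recovers to 1e-12; the contact channels
  # shrink to ~mOhm at the top of the band, where forming u1 - u2 cancels
  # catastrophically, so they are held to a slightly looser machine-level bound
  expect_lt(max(Mod(got$Zbody - want$Zbody) / Mod(want$Zbody)), 1e-12)
  expect_lt(max(Mod(got$Z - want$Z) / Mod(want$Z)), 1e-12)
  for (cc in c("Zin", "Zout")) {
    rel <- Mod(got[[cc]] - want[[cc]]) / Mod(want[[cc]])
    expect_lt(max(rel), 1e-10)
  }
})

test_that("phantom config validates components and tolerances", {
  expect_error(phantom_config(body_Rinf = -1), "positive")
  expect_error(phantom_config(r_tolerance = 0.5), "Tolerances")
  expect_error(solve_node_phasors(nominal_phantom(), 1, v_gen = 0), "v_gen")
})
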