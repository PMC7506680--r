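test_that("relative error spectra follow the percent-modulus definition", {
  cfg <- nominal_phantom()
  f <- c(0.01, 1, 100)
  theo <- phantom_impedances(cfg, f)
  expect_equal(unlist(relative_errors(theo, cfg)[, -1]),
               setNames(rep(0, 12), NULL), ignore_attr = TRUE)
  inflated <- theo
  inflated$Zbody <- 1.03 * theo$Zbody
  err <- relative_errors(inflated, cfg)
  expect_equal(err$eps_body, rep(3, 3), tolerance = 1e-12)
  expect_equal(max_relative_errors(err)$eps_body, 3, tolerance = 1e-12)
})

test_that("the noiseless 40-point pipeline sits far below the instrument's measured error bound", {
  cfg <- nominal_phantom()
  plan <- plan_sweep(1e-3, 1e5, 5)
  spec <- extract_impedances(run_sweep(cfg, plan), cfg$Rref)
  err <- max_relative_errors(relative_errors(spec, cfg))
  expect_lt(err$eps_body, 3.016)   # physical-instrument bound
  expect_lt(err$eps_body, 1e-6)    # simulation should be essentially exact
})

test_that("fitting the noiseless 40-point spectrum recovers the phantom parameters", {
  cfg <- nominal_phantom()
  truth <- phantom_body_params(cfg)
  spec <- phantom_impedances(cfg, plan_sweep(1e-3, 1e5, 5)$freq_hz)
  fit <- fit_cole_cole(spec)
  expect_true(fit$converged)
  expect_gte(fit$r_squared, 0.99991)
  pe <- parameter_errors(fit, truth)
  expect_true(all(pe$error_pct <= 0.01))
  expect_equal(coef(fit)[["a"]], 1, tolerance = 1e-4)
})

test_that("synthetic constant-phase-element spectra are recovered to 0.1%", {
  truth <- cole_cole_params(R0 = 11000, Rinf = 1000, tau = 0.1, a = 0.8)
  f <- plan_sweep(1e-3, 1e5, 5)$freq_hz
  dat <- tibble::tibble(freq_hz = f, Zbody = cole_cole_impedance(truth, f))
  fit <- fit_cole_cole(dat)
  expect_true(fit$converged)
  expect_true(all(parameter_errors(fit, truth)$error_pct <= 0.1))
  # refitting from the converged solution is idempotent
  fit2 <- fit_cole_cole(dat, init = fit$params)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-6)
})

test_that("degenerate spectra are flagged as non-converged, not errors", {
  f <- 10^seq(-2, 2, length.out = 10)
  flat <- tibble::tibble(freq_hz = f, Zbody = complex(real = rep(500, 10)))
  fit <- fit_cole_cole(flat)
  expect_false(fit$converged)
  expect_true(all(is.na(coef(fit))))
  expect_error(predict(fit), "converged")
  expect_error(fit_cole_cole(flat[1:3, ]), "4")
})

test_that("fit accessors expose tidy parameter and summary tables", {
  truth <- cole_cole_params(11000, 1000, 0.1, 0.9)
  f <- 10^seq(-3, 4, length.out = 30)
  fit <- fit_cole_cole(tibble::tibble(freq_hz = f,
                                      Zbody = cole_cole_impedance(truth, f)))
  td <- tidy(fit)
  expect_identical(td$term, c("R0", "Rinf", "tau", "a"))
  expect_equal(td$estimate, unname(coef(fit)))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_equal(predict(fit, 0), complex(real = 11000), tolerance = 1e-3)
})

test_that("parameter relative errors reproduce the published worked examples", {
  truth <- cole_cole_params(R0 = 11000, Rinf = 1000, tau = 0.1, a = 1)
  # 40-point recording, first repeat
  m1 <- cole_cole_params(R0 = 11107, Rinf = 996.31, tau = 0.1017, a = 0.9687)
  e1 <- parameter_errors(m1, truth)
  expect_equal(round(e1$error_pct[e1$term == "Rinf"], 2), 0.37)
  expect_identical(parameter_errors(truth, truth)$error_pct, rep(0, 4))
})

test_that("goodness of fit matches a brute-force stacked-residual computation", {
  model <- c(1 + 2i, 2 + 1i, 4 - 1i)
  data <- c(1.1 + 1.9i, 2.2 + 1.2i, 3.8 - 0.9i)
  expect_equal(goodness_of_fit(model, data),
               r_squared_bruteforce(model, data), tolerance = 1e-14)
  expect_equal(goodness_of_fit(data, data), 1)
  expect_equal(goodness_of_fit(rep(mean(data), 3), data), 0)
  # invariant to a common real scale
  expect_equal(goodness_of_fit(10 * model, 10 * data),
               goodness_of_fit(model, data), tolerance = 1e-12)
  expect_error(goodness_of_fit(model[1:2], data), "length")
  expect_error(goodness_of_fit(c(1 + 0i, 1 + 0i), c(2 + 0i, 2 + 0i)), "zero")
})

test_that("parameter averaging reproduces the published summary row", {
  tab1 <- data.frame(
    a = c(0.9687, 0.9867, 0.9796, 0.9845, 0.9833),
    tau = c(0.1017, 0.0993, 0.1002, 0.0996, 0.0998),
    R0 = c(11107, 10941, 11006, 10965, 10976),
    Rinf = c(996.31, 1004.2, 1001.2, 1003.2, 1002.7))
  avg <- summarize_parameters(tab1)
  expect_equal(round(avg$a, 4), 0.9806)
  expect_equal(round(avg$Rinf, 1), 1001.5)
  expect_identical(avg$n_fits, 5L)
  expect_error(summarize_parameters(data.frame(a = 1, tau = 1, R0 = 2,
                                               Rinf = 1,
                                               converged = FALSE)),
               "converged")
})

test_that("noisy simulated sweeps still recover parameters within tolerance", {
  cfg <- nominal_phantom()
  truth <- phantom_body_params(cfg)
  plan <- plan_sweep(1e-3, 1e5, 5)
  worst <- purrr::map_dfr(1:5, function(s) {
    nm <- noise_model(white_rms = 3.2e-5, harmonic_levels = list(), seed = s)
    spec <- extract_impedances(run_sweep(cfg, plan, noise = nm), cfg$Rref)
    fit <- fit_cole_cole(spec)
    expect_true(fit$converged)
    parameter_errors(fit, truth)
  })
  by_term <- dplyr::summarise(dplyr::group_by(worst, term),
                              worst = max(error_pct))
  expect_lte(by_term$worst[by_term$term == "a"], 5)
  expect_lte(by_term$worst[by_term$term == "tau"], 1)
  expect_lte(by_term$worst[by_term$term == "R0"], 1)
  expect_lte(by_term$worst[by_term$term == "Rinf"], 1)
})
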