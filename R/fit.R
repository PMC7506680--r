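#' Goodness of fit of a complex spectrum
#'
#' \eqn{R^2 = 1 - \sum_i |\hat Z_i - Z_i'|^2 / \sum_i |\bar Z' - Z_i'|^2},
#' where the squared complex moduli stack the real and imaginary residuals
#' and \eqn{\bar Z'} is the complex mean of the data. Invariant to a common
#' real scale on model and data.
#'
#' @param model_values Complex model impedances (ohms).
#' @param data_values Complex measured impedances, same length >= 2.
#' @return Dimensionless R-squared.
#' @export
goodness_of_fit <- function(model_values, data_values) {
  model_values <- as.complex(model_values)
  data_values <- as.complex(data_values)
  n <- length(data_values)
  if (length(model_values) != n || n < 2)
    abort("Model and data must have equal length >= 2.")
  ss_tot <- sum(Mod(mean(data_values) - data_values)^2)
  if (ss_tot == 0) abort("Total sum of squares is zero (constant data).")
  1 - sum(Mod(model_values - data_values)^2) / ss_tot
}

#' Fit the Cole--Cole model to an impedance spectrum
#'
#' Levenberg--Marquardt least squares of the four-parameter Cole--Cole
#' model against complex impedance data, with residuals stacked over real
#' and imaginary parts (unweighted); a magnitude-only residual is available
#' for sensitivity analysis. `Rinf`, the resistance increment
#' `dR = R0 - Rinf` and `tau` are optimized on the log scale (which
#' enforces positivity and `R0 > Rinf`); the exponent `a` is box-bounded
#' in (0, 1].
#'
#' Default initialization is data-driven: `Rinf` from `|Z|` at the highest
#' frequency, `R0` from `|Z|` at the lowest, `tau = 1/(2*pi*f*)` with `f*`
#' the frequency of the largest `|Im Z|`, and `a = 0.9`.
#'
#' Non-convergence (including degenerate, dispersion-free spectra) is
#' reported through the `converged` flag rather than an error.
#'
#' @param data A data frame with a frequency column and either a complex
#'   impedance column or `re_ohm`/`im_ohm` columns.
#' @param z_col Name of the complex impedance column (default `"Zbody"`).
#' @param freq_col Name of the frequency column (default `"freq_hz"`).
#' @param init Optional [cole_cole_params()] starting point.
#' @param residuals `"stacked"` (default) or `"magnitude"`.
#' @return A `cole_cole_fit` object: `params` ([cole_cole_params()]),
#'   `r_squared`, `residual_norm`, `n_points`, `converged`, plus the data
#'   and solver diagnostics. Methods: `print`, `coef`, `predict`, [tidy()],
#'   [glance()], [autoplot()].
#' @examples
#' spec <- phantom_impedances(phantom_config(),
#'                            plan_sweep(1e-3, 1e5, 5)$freq_hz)
#' fit <- fit_cole_cole(spec)
#' glance(fit)
#' @export
fit_cole_cole <- function(data, z_col = "Zbody", freq_col = "freq_hz",
                          init = NULL, residuals = c("stacked", "magnitude")) {
  residuals <- match.arg(residuals)
  stopifnot(is.data.frame(data), freq_col %in% names(data))
  freq <- data[[freq_col]]
  if (z_col %in% names(data)) {
    z <- as.complex(data[[z_col]])
  } else if (all(c("re_ohm", "im_ohm") %in% names(data))) {
    z <- complex(real = data$re_ohm, imaginary = data$im_ohm)
  } else {
    abort(sprintf("No impedance column `%s` (or re_ohm/im_ohm) found.", z_col))
  }
  keep <- is.finite(freq) & freq > 0 & is.finite(Re(z)) & is.finite(Im(z))
  freq <- freq[keep]; z <- z[keep]
  n <- length(z)
  if (n < 4) abort("At least 4 positive-frequency points are required.")

  if (is.null(init)) {
    o <- order(freq)
    rinf0 <- max(Mod(z[o][n]), .Machine$double.eps)
    r00 <- max(Mod(z[o][1]), rinf0 * (1 + 1e-3))
    fstar <- freq[which.max(abs(Im(z)))]
    init <- list(Rinf = rinf0, R0 = r00, tau = 1 / (2 * pi * fstar), a = 0.9)
  } else {
    stopifnot(inherits(init, "cole_cole_params"))
  }
  par0 <- c(log_rinf = log(init$Rinf),
            log_dr = log(max(init$R0 - init$Rinf, 1e-9 * init$Rinf)),
            log_tau = log(init$tau),
            a = init$a)

  model_z <- function(p, f) {
    rinf <- exp(p[["log_rinf"]]); dr <- exp(p[["log_dr"]])
    tau <- exp(p[["log_tau"]]); a <- p[["a"]]
    rinf + dr / (1 + (1i * 2 * pi * f * tau)^a)
  }
  resid_fn <- function(p) {
    zm <- model_z(p, freq)
    if (residuals == "stacked") c(Re(zm - z), Im(zm - z))
    else Mod(zm) - Mod(z)
  }

  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = par0, fn = resid_fn,
      lower = c(-Inf, -Inf, -Inf, 1e-3),
      upper = c(Inf, Inf, Inf, 1),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) NULL)

  if (is.null(fit)) {
    params <- NULL
    converged <- FALSE
    r2 <- NA_real_
    rnorm_ <- NA_real_
    info <- -1L
    message_ <- "solver error"
  } else {
    p <- fit$par
    rinf <- exp(p[["log_rinf"]]); dr <- exp(p[["log_dr"]])
    tau <- exp(p[["log_tau"]]); a <- min(max(p[["a"]], 1e-3), 1)
    zm <- model_z(p, freq)
    r2 <- tryCatch(goodness_of_fit(zm, z), error = function(e) NA_real_)
    rnorm_ <- sqrt(sum(Mod(zm - z)^2))
    info <- fit$info
    message_ <- fit$message
    # A dispersion-free (flat) spectrum drives dR to zero; flag rather than
    # report a meaningless parameter set.
    sane <- info %in% 1:4 && is.finite(dr) && dr > 1e-6 * rinf &&
      is.finite(tau) && tau > 0
    converged <- isTRUE(sane)
    params <- if (converged)
      cole_cole_params(R0 = rinf + dr, Rinf = rinf, tau = tau, a = a)
    else NULL
  }

  structure(list(params = params, r_squared = r2, residual_norm = rnorm_,
                 n_points = n, converged = converged,
                 residual_type = residuals,
                 freq_hz = freq, z = z,
                 solver_info = info, solver_message = message_),
            class = "cole_cole_fit")
}

#' @export
print.cole_cole_fit <- function(x, ...) {
  cat("<cole_cole_fit>", if (x$converged) "converged" else "NOT converged",
      sprintf("(%d points)\n", x$n_points))
  if (x$converged) {
    with(x$params, cat(sprintf(
      "  R0 = %.6g Ohm, Rinf = %.6g Ohm, tau = %.6g s, a = %.6g\n",
      R0, Rinf, tau, a)))
    cat(sprintf("  R^2 = %.7f, residual norm = %.4g Ohm\n",
                x$r_squared, x$residual_norm))
  } else {
    cat("  ", x$solver_message, "\n")
  }
  invisible(x)
}

#' @export
coef.cole_cole_fit <- function(object, ...) {
  if (!object$converged) return(c(R0 = NA_real_, Rinf = NA_real_,
                                  tau = NA_real_, a = NA_real_))
  with(object$params, c(R0 = R0, Rinf = Rinf, tau = tau, a = a))
}

#' @export
predict.cole_cole_fit <- function(object, freq = NULL, ...) {
  if (!object$converged) abort("Cannot predict from a non-converged fit.")
  freq <- freq %||% object$freq_hz
  cole_cole_impedance(object$params, freq)
}

#' Tidy a Cole--Cole fit into one row per parameter
#'
#' @param x A `cole_cole_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @method tidy cole_cole_fit
#' @export
tidy.cole_cole_fit <- function(x, ...) {
  tibble(term = c("R0", "Rinf", "tau", "a"),
         estimate = unname(coef(x)))
}

#' One-row fit summary
#'
#' @param x A `cole_cole_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `r_squared`, `residual_norm`, `n_points`,
#'   `converged`.
#' @method glance cole_cole_fit
#' @export
glance.cole_cole_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, residual_norm = x$residual_norm,
         n_points = x$n_points, converged = x$converged)
}

#' Bode-style plot of a Cole--Cole fit
#'
#' Magnitude (and phase) of the fitted model over the data.
#'
#' @param object A `cole_cole_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cole_cole_fit
#' @export
autoplot.cole_cole_fit <- function(object, ...) {
  dat <- tibble(freq_hz = object$freq_hz,
                magnitude_ohm = Mod(object$z),
                which = "measured")
  if (object$converged) {
    fgrid <- 10^seq(log10(min(object$freq_hz)), log10(max(object$freq_hz)),
                    length.out = 200)
    dat <- dplyr::bind_rows(dat, tibble(
      freq_hz = fgrid,
      magnitude_ohm = Mod(cole_cole_impedance(object$params, fgrid)),
      which = "fitted"))
  }
  ggplot2::ggplot(dat, ggplot2::aes(.data$freq_hz, .data$magnitude_ohm,
                                    colour = .data$which,
                                    linetype = .data$which)) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$which == "fitted")) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$which == "measured"),
                        size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "|Z| (Ohm)",
                  colour = NULL, linetype = NULL,
                  title = "Cole-Cole fit")
}
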