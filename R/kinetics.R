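# Two-substrate Michaelis-Menten kinetics of the NADPH-dependent
# alkenal/one oxidoreductase (AOR, EC 1.3.1.74) reducing MVK to MEK,
# with a single-optimum temperature response; forward model and
# initial-slope fitting of A340 assay traces.

#' Kinetic parameter set for the AOR reaction
#'
#' @param vmax maximal velocity at the temperature optimum, mM min-1.
#' @param km_mvk Michaelis constant for the substrate MVK, mM.
#' @param km_nadph Michaelis constant for the cofactor NADPH, mM.
#' @param t_opt temperature optimum, degrees C.
#' @param t_width breadth of the Gaussian temperature response, degrees C.
#' @return object of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(vmax, km_mvk = 14.15, km_nadph = 0.049,
                               t_opt = 35, t_width = 10) {
  if (vmax < 0) stop("vmax must be >= 0")
  if (km_mvk <= 0 || km_nadph <= 0) stop("Km values must be > 0")
  if (t_width <= 0) stop("t_width must be > 0")
  structure(list(vmax = vmax, km_mvk = km_mvk, km_nadph = km_nadph,
                 t_opt = t_opt, t_width = t_width),
            class = "kinetic_parameters")
}

# Gaussian temperature response, = 1 at the optimum
.temp_response <- function(temperature, t_opt, t_width) {
  exp(-0.5 * ((temperature - t_opt) / t_width)^2)
}

#' AOR reaction velocity
#'
#' Multiplicative two-substrate Michaelis-Menten form with a Gaussian
#' temperature response normalised to 1 at the optimum:
#' \deqn{v = V_{max} \frac{S}{K_m^S + S} \frac{N}{K_m^N + N} g(T).}
#'
#' @param params a [kinetic_parameters()] object.
#' @param mvk substrate (MVK) concentration, mM.
#' @param nadph cofactor (NADPH) concentration, mM.
#' @param temperature assay temperature, degrees C; default the optimum.
#' @return velocity, mM min-1 (vectorised over the concentration inputs).
#' @export
aor_rate <- function(params, mvk, nadph, temperature = params$t_opt) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (any(mvk < 0) || any(nadph < 0)) stop("concentrations must be >= 0")
  params$vmax * mvk / (params$km_mvk + mvk) *
    nadph / (params$km_nadph + nadph) *
    .temp_response(temperature, params$t_opt, params$t_width)
}

#' Predicted A340 assay slope
#'
#' NADPH consumption is monitored at 340 nm, so the absorbance slope is
#' \eqn{dA/dt = -\varepsilon\,\ell\,v}. The control without substrate
#' (`mvk = 0`) has zero slope.
#'
#' @inheritParams aor_rate
#' @param epsilon_nadph NADPH molar absorptivity at 340 nm, AU mM-1 cm-1.
#' @param path_length optical path, cm.
#' @return dA340/dt, AU min-1.
#' @export
assay_slope <- function(params, mvk, nadph, temperature = params$t_opt,
                        epsilon_nadph = 6.22, path_length = 1) {
  -epsilon_nadph * path_length *
    aor_rate(params, mvk, nadph, temperature)
}

# initial slope of each trace by ordinary least squares
.trace_slopes <- function(traces) {
  do.call(rbind, lapply(split(traces, traces$trace_id), function(d) {
    fit <- stats::lm.fit(cbind(1, d$time), d$absorbance)
    data.frame(trace_id = d$trace_id[1], slope = fit$coefficients[2],
               mvk = d$mvk_conc[1], nadph = d$nadph_conc[1],
               temperature = d$temperature[1],
               rate = -fit$coefficients[2] /
                 (d$epsilon_nadph[1] * d$path_length[1]))
  }))
}

#' Fit AOR kinetic parameters from assay traces
#'
#' Extracts the initial slope of each absorbance trace by linear
#' regression, converts slopes to velocities through the configured molar
#' absorptivity and path length, and fits the two-substrate
#' Michaelis-Menten model by nonlinear least squares
#' ([minpack.lm::nlsLM()]). The temperature response (`t_opt`, `t_width`)
#' is fitted only when the traces span at least three distinct
#' temperatures; otherwise the response factor at the (single) assay
#' temperature is absorbed into `vmax` and the supplied values are kept.
#'
#' @param traces assay traces in the [gen_assay_traces()] schema.
#' @param start optional named list of starting values.
#' @param t_opt,t_width fallback temperature-response parameters when the
#'   design does not constrain them.
#' @return list of class `kinetics_fit`: `params`
#'   ([kinetic_parameters()]), `se` (named standard errors), `converged`,
#'   `fitted_temperature_response`, `residual_sd`, and `fit` (the nls
#'   object).
#' @export
fit_kinetics <- function(traces, start = NULL, t_opt = 35, t_width = 10) {
  sl <- .trace_slopes(traces)
  if (length(unique(sl$mvk)) < 4 || length(unique(sl$nadph)) < 4)
    stop("design is rank-deficient: need >= 4 distinct concentrations ",
         "per substrate")
  fit_temp <- length(unique(sl$temperature)) >= 3
  if (is.null(start))
    start <- list(vmax = max(sl$rate) * 2, km_mvk = stats::median(sl$mvk),
                  km_nadph = stats::median(sl$nadph))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500)
  fit <- if (fit_temp) {
    st <- c(start, list(t_opt = t_opt, t_width = t_width))
    minpack.lm::nlsLM(
      rate ~ vmax * mvk / (km_mvk + mvk) * nadph / (km_nadph + nadph) *
        exp(-0.5 * ((temperature - t_opt) / t_width)^2),
      data = sl, start = st,
      lower = c(0, 1e-9, 1e-9, -50, 0.1), control = ctrl)
  } else {
    minpack.lm::nlsLM(
      rate ~ vmax * mvk / (km_mvk + mvk) * nadph / (km_nadph + nadph),
      data = sl, start = start, lower = c(0, 1e-9, 1e-9), control = ctrl)
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  converged <- fit$convInfo$isConv
  if (!isTRUE(converged))
    warning("kinetics fit did not converge; result flagged")
  params <- kinetic_parameters(
    vmax = cf[["vmax"]], km_mvk = cf[["km_mvk"]], km_nadph = cf[["km_nadph"]],
    t_opt = if (fit_temp) cf[["t_opt"]] else t_opt,
    t_width = if (fit_temp) cf[["t_width"]] else t_width)
  structure(list(params = params, se = se, converged = isTRUE(converged),
                 fitted_temperature_response = fit_temp,
                 residual_sd = stats::sd(stats::residuals(fit)),
                 fit = fit),
            class = "kinetics_fit")
}

#' Recommended saturating assay concentration from a Michaelis constant
#'
#' The working-assay convention of running the cofactor at three times its
#' Michaelis constant, rounded to the assay's two-decimal pipetting
#' precision (mM).
#'
#' @param km Michaelis constant, mM.
#' @param multiple saturation multiple (default 3).
#' @param digits rounding precision (default 2).
#' @return concentration, mM.
#' @export
recommended_assay_concentration <- function(km, multiple = 3, digits = 2) {
  if (km <= 0) stop("km must be > 0")
  round(multiple * km, digits)
}
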