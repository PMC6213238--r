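#' First-order biodegradation kinetics
#'
#' The package's core model is single-pool first-order loss of organic matter,
#' \deqn{dC/dt = L - kC,} with decay constant \eqn{k} (per year), half-life
#' \eqn{T_{0.5} = \ln 2 / k} and 95\%-decay time \eqn{T_{0.95} \approx 3/k}.
#' A `kinetic_estimate` bundles a decay constant with its derived
#' characteristic times, the yearly period of biological activity it assumes,
#' and the provenance of the estimate.
#'
#' @param k decay constant, per year (>= 0; 0 means no measurable decay and
#'   infinite characteristic times).
#' @param t_bio period of biological activity, days per year (0, 365].
#' @param source one of `"respiration"`, `"annual_loss"`, `"series_fit"`.
#' @param r_squared coefficient of determination when the estimate comes from
#'   a regression, otherwise `NA`.
#' @return An object of class `kinetic_estimate`: a list with elements `k`,
#'   `t_half`, `t_95` (years), `t_bio` (days), `source`, `r_squared`.
#' @examples
#' kinetic_estimate(0.712, source = "series_fit")
#' @export
kinetic_estimate <- function(k, t_bio = 365,
                             source = c("respiration", "annual_loss",
                                        "series_fit"),
                             r_squared = NA_real_) {
  check_number(k, "k", lower = 0)
  check_number(t_bio, "t_bio", lower = 0, upper = 365, allow_lower = FALSE)
  source <- match.arg(source)
  structure(list(k = k,
                 t_half = if (k > 0) log(2) / k else Inf,
                 t_95 = if (k > 0) 3 / k else Inf,
                 t_bio = t_bio,
                 source = source,
                 r_squared = r_squared),
            class = "kinetic_estimate")
}

#' @export
print.kinetic_estimate <- function(x, ...) {
  cat("First-order biodegradation estimate (", x$source, ")\n", sep = "")
  cat(sprintf("  k      = %.4g yr^-1\n", x$k))
  cat(sprintf("  T0.5   = %.1f yr\n", x$t_half))
  cat(sprintf("  T0.95  = %.1f yr\n", x$t_95))
  cat(sprintf("  T_bio  = %g days\n", x$t_bio))
  if (!is.na(x$r_squared)) cat(sprintf("  R^2    = %.3f\n", x$r_squared))
  invisible(x)
}

#' Convert a CO2-based flux to a carbon-based flux
#'
#' Multiplies a respiration rate expressed as mg CO2 per kg per hour by the
#' molar-mass ratio 12/44 to obtain mg C per kg per hour, the canonical flux
#' unit used by [k_from_respiration()].
#'
#' @param u_co2 respiration rate, mg CO2 kg^-1 h^-1 (>= 0).
#' @return Carbon emission rate, mg C kg^-1 h^-1.
#' @export
carbon_flux_from_co2 <- function(u_co2) {
  check_numeric_vector(u_co2, "u_co2", lower = 0)
  u_co2 * 12 / 44
}

#' Decay constant from basal respiration
#'
#' Converts a carbon emission rate measured under optimum incubation
#' conditions into a first-order biodegradation constant. The daily fractional
#' carbon loss is \eqn{p = 24 \cdot 10^{-2} U_c / C_\%} (percent of the organic
#' carbon stock per day), and
#' \deqn{k = (T_b / T_0)\,[\ln 100 - \ln(100 - p)],}
#' with \eqn{T_0} fixed at one year and \eqn{T_b} the yearly period of
#' biological activity in days. For a CO2-based flux apply
#' [carbon_flux_from_co2()] first (or use [k_from_co2_respiration()]).
#'
#' @param u_carbon carbon emission rate, mg C kg^-1 h^-1 (>= 0).
#' @param c_percent organic carbon content, percent of dry mass (0, 100].
#' @param t_bio period of biological activity, days (default 365: potential
#'   rates under permanently optimal conditions).
#' @return A [kinetic_estimate()] with `source = "respiration"`.
#' @examples
#' k_from_respiration(30, 30)  # upper corner of the peat range, k ~ 0.88
#' @export
k_from_respiration <- function(u_carbon, c_percent, t_bio = 365) {
  check_number(u_carbon, "u_carbon", lower = 0)
  check_number(c_percent, "c_percent", lower = 0, upper = 100,
               allow_lower = FALSE)
  p <- 24e-2 * u_carbon / c_percent
  if (p >= 100)
    stop_invalid("daily loss p = ", format(p),
                 "% >= 100%: the sample would vanish within a day; ",
                 "check flux and carbon-content units")
  k <- (t_bio / 1) * (log(100) - log(100 - p))
  kinetic_estimate(k, t_bio = t_bio, source = "respiration")
}

#' @rdname k_from_respiration
#' @param u_co2 respiration rate, mg CO2 kg^-1 h^-1; converted by 12/44.
#' @export
k_from_co2_respiration <- function(u_co2, c_percent, t_bio = 365) {
  check_number(u_co2, "u_co2", lower = 0)
  k_from_respiration(carbon_flux_from_co2(u_co2), c_percent, t_bio)
}

#' Decay constant from an observed annual loss fraction
#'
#' Inverts one year of exponential decay: a fraction `loss_fraction` of the
#' stock lost per year corresponds to \eqn{k = -\ln(1 - \mathrm{loss})}.
#'
#' @param loss_fraction fraction of the stock lost per year, in [0, 1).
#' @return A [kinetic_estimate()] with `source = "annual_loss"`.
#' @examples
#' k_from_annual_loss(0.10)  # 10 percent per year -> k ~ 0.105 (prints 0.11)
#' @export
k_from_annual_loss <- function(loss_fraction) {
  check_number(loss_fraction, "loss_fraction", lower = 0, upper = 1,
               allow_upper = FALSE)
  kinetic_estimate(-log(1 - loss_fraction), source = "annual_loss")
}

#' Characteristic decay times
#'
#' @param k decay constant, per year (> 0).
#' @return Named numeric vector `c(t_half, t_95)` in years:
#'   \eqn{\ln 2 / k} and \eqn{3 / k}. Their ratio is always
#'   \eqn{3/\ln 2 \approx 4.328}.
#' @examples
#' characteristic_times(0.712)  # half-life ~ 1 year
#' @export
characteristic_times <- function(k) {
  check_number(k, "k", lower = 0, allow_lower = FALSE)
  c(t_half = log(2) / k, t_95 = 3 / k)
}

#' Exponential decay curve
#'
#' Analytical solution of \eqn{dC/dt = -kC}: \eqn{C(t) = C_0 e^{-kt}}.
#'
#' @param c0 initial amount (>= 0, any unit).
#' @param k decay constant, per year (>= 0).
#' @param t time, years (>= 0, vectorised).
#' @return Remaining amount at each `t`.
#' @export
decay_curve <- function(c0, k, t) {
  check_number(c0, "c0", lower = 0)
  check_number(k, "k", lower = 0)
  check_numeric_vector(t, "t", lower = 0)
  c0 * exp(-k * t)
}

#' Required steady-state input flux
#'
#' At steady state of \eqn{dC/dt = L - kC} the surface input must balance the
#' annual decomposition emission: \eqn{L = k C}.
#'
#' @param k decay constant, per year (>= 0).
#' @param stock standing stock, g m^-2 (or kg m^-2; output inherits the unit).
#' @return Required input flux, same mass unit per m^2 per year.
#' @export
steady_state_input <- function(k, stock) {
  check_number(k, "k", lower = 0)
  check_number(stock, "stock", lower = 0)
  k * stock
}

# ---- mass-loss series ------------------------------------------------------

#' Mass-loss (or carbon-content) time series
#'
#' Field decomposition series: percent of initial mass retained,
#' \eqn{D_\% = 100\, m_t / m_0}, or organic-carbon content per time point.
#'
#' @param times years since start, strictly increasing, first value 0 allowed.
#' @param values percent retained (mass kind, starts at 100) or carbon
#'   content in percent of the construction mass (carbon kind, starts at the
#'   applied dose).
#' @param kind `"mass"` or `"carbon"`.
#' @return Object of class `mass_loss_series` (a data.frame with columns
#'   `time_years`, `value_percent` and attribute `kind`).
#' @export
mass_loss_series <- function(times, values, kind = c("mass", "carbon")) {
  kind <- match.arg(kind)
  check_numeric_vector(times, "times", lower = 0)
  check_numeric_vector(values, "values", lower = 0)
  if (length(times) != length(values))
    stop_invalid("`times` and `values` must have equal length")
  if (is.unsorted(times, strictly = TRUE))
    stop_invalid("`times` must be strictly increasing")
  if (kind == "mass" && abs(values[1] - 100) > 1e-6)
    warning("mass-loss series does not start at 100% retained (",
            format(values[1]), ")", call. = FALSE)
  structure(data.frame(time_years = times, value_percent = values),
            kind = kind, class = c("mass_loss_series", "data.frame"))
}

#' Fit a first-order decay constant to a mass-loss series
#'
#' Nonlinear least squares of \eqn{y(t) = y_0 e^{-kt}} on the natural scale
#' (matching exponential-regression fits of the analytical decay solution).
#' `y0` is fixed to the first observation by default or co-fitted; a
#' log-linear regression is available as an alternative estimator.
#'
#' @param series a [mass_loss_series()] with at least 3 points.
#' @param fix_y0 if `TRUE` (default) the intercept is pinned to the first
#'   observed value; if `FALSE`, `y0` is co-fitted.
#' @param log_linear if `TRUE` fit by linear regression of `log(y)` on `t`
#'   instead of nonlinear least squares.
#' @return A [kinetic_estimate()] with `source = "series_fit"` and `r_squared`
#'   computed on the natural scale; attributes `y0`, `residuals` and `fitted`
#'   carry the fit details.
#' @examples
#' s <- mass_loss_series(c(0, 0.5, 1, 1.5, 2), 100 * exp(-0.77 * c(0, 0.5, 1, 1.5, 2)))
#' fit_decay_constant(s)$k  # 0.77
#' @export
fit_decay_constant <- function(series, fix_y0 = TRUE, log_linear = FALSE) {
  if (!inherits(series, "mass_loss_series"))
    stop_invalid("`series` must be a mass_loss_series")
  t <- series$time_years
  y <- series$value_percent
  if (length(t) < 3L)
    stop_invalid("at least 3 time points are required to fit a decay constant")
  if (all(diff(y) >= 0))
    warning("series shows no loss; decay constant clipped at 0",
            call. = FALSE)

  # log-linear slope as starting value (guard against non-positive values)
  pos <- y > 0
  k0 <- if (sum(pos) >= 2) max(-unname(stats::coef(
    stats::lm(log(y[pos]) ~ t[pos]))[2]), 1e-8) else 1e-8

  if (log_linear) {
    if (any(y <= 0))
      stop_fit("log-linear fit requires strictly positive values")
    fit <- stats::lm(log(y) ~ t)
    k <- max(-unname(stats::coef(fit)[2]), 0)
    y0 <- if (fix_y0) y[1] else exp(unname(stats::coef(fit)[1]))
  } else if (fix_y0) {
    y0 <- y[1]
    dat <- data.frame(t = t, y = y)
    fit <- minpack.lm::nlsLM(y ~ y0 * exp(-k * t), data = dat,
                             start = list(k = k0), lower = 0,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    k <- unname(stats::coef(fit)["k"])
  } else {
    dat <- data.frame(t = t, y = y)
    fit <- minpack.lm::nlsLM(y ~ y0 * exp(-k * t), data = dat,
                             start = list(y0 = max(y[1], 1e-8), k = k0),
                             lower = c(1e-12, 0),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    k <- unname(stats::coef(fit)["k"])
    y0 <- unname(stats::coef(fit)["y0"])
  }
  fitted <- y0 * exp(-k * t)
  est <- kinetic_estimate(k, source = "series_fit",
                          r_squared = r_squared(y, fitted))
  attr(est, "y0") <- y0
  attr(est, "fitted") <- fitted
  attr(est, "residuals") <- y - fitted
  est
}

# ---- serialization ---------------------------------------------------------

#' Read and write mass-loss series and kinetic estimates
#'
#' Series are delimited text with header `time_years,value_percent`; kinetic
#' estimates are JSON with keys `k`, `t_half`, `t_95`, `t_bio`, `source`,
#' `r_squared`.
#'
#' @param path file path.
#' @param series a [mass_loss_series()].
#' @param kind series kind to assume on read.
#' @name kinetics-io
NULL

#' @rdname kinetics-io
#' @export
read_mass_loss <- function(path, kind = c("mass", "carbon")) {
  d <- load_dataset(path, c(time_years = "numeric", value_percent = "numeric"))
  mass_loss_series(d$time_years, d$value_percent, kind = match.arg(kind))
}

#' @rdname kinetics-io
#' @export
write_mass_loss <- function(series, path) {
  if (!inherits(series, "mass_loss_series"))
    stop_invalid("`series` must be a mass_loss_series")
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname kinetics-io
#' @param estimate a [kinetic_estimate()].
#' @export
write_kinetic_estimate <- function(estimate, path) {
  if (!inherits(estimate, "kinetic_estimate"))
    stop_invalid("`estimate` must be a kinetic_estimate")
  jsonlite::write_json(unclass(estimate), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}
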