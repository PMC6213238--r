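#' Temperature response of biodegradation
#'
#' Q10-type temperature factor \eqn{m(T) = Q_{10}^{(T - T_m)/10}} on the
#' stated domain 0 <= T <= T_m. Q10 is the multiplicative rate increase per
#' 10 C; on average it can be taken equal to two. T_m is the optimum
#' temperature (default 30 C).
#'
#' @param q10 temperature coefficient (> 1).
#' @param t_opt optimum temperature, C.
#' @param u_max rate at the optimum, mg kg^-1 h^-1 (optional until a surface
#'   is evaluated).
#' @return Object of class `temperature_response`.
#' @export
temperature_response <- function(q10 = 2, t_opt = 30, u_max = NA_real_) {
  check_number(q10, "q10", lower = 1, allow_lower = FALSE)
  check_number(t_opt, "t_opt", lower = -273.15)
  if (!is.na(u_max)) check_number(u_max, "u_max", lower = 0)
  structure(list(q10 = q10, t_opt = t_opt, u_max = u_max),
            class = "temperature_response")
}

#' Moisture response of biodegradation
#'
#' Extremum moisture factor on relative moisture \eqn{W/W_s \in (0, 1]}:
#' \deqn{f(W) = (W/W_m)^a \left(\frac{1 - W}{1 - W_m}\right)^b,}
#' where \eqn{W_m = a/(a + b)} is the moisture at the rate maximum. The
#' extremum point is an algebraic identity of the exponents, making the model
#' effectively two-parameter.
#'
#' @param a,b positive empirical exponents.
#' @param u_max rate at the optimum (optional).
#' @return Object of class `moisture_response` with redundant field `w_opt`
#'   = a/(a+b), checked on construction.
#' @examples
#' moisture_response(4.84, 2.35)$w_opt  # 0.673
#' @export
moisture_response <- function(a, b, u_max = NA_real_) {
  check_number(a, "a", lower = 0, allow_lower = FALSE)
  check_number(b, "b", lower = 0, allow_lower = FALSE)
  if (!is.na(u_max)) check_number(u_max, "u_max", lower = 0)
  structure(list(a = a, b = b, w_opt = a / (a + b), u_max = u_max),
            class = "moisture_response")
}

#' @export
format.moisture_response <- function(x, digits = 3, ...) {
  sprintf("f(W) = (W/%s)^%s * ((1 - W)/%s)^%s",
          format(x$w_opt, digits = digits), format(x$a, digits = digits),
          format(1 - x$w_opt, digits = digits), format(x$b, digits = digits))
}

#' @export
print.moisture_response <- function(x, ...) {
  cat("Moisture response:", format(x), "\n")
  if (!is.na(x$u_max)) cat(sprintf("  u_max = %.4g mg/kg/h\n", x$u_max))
  invisible(x)
}

#' Exponential temperature law for the decay constant
#'
#' \eqn{k(T) = k_0 e^{sT}} with k0 in per year and s per degree C. The implied
#' Q10 is \eqn{e^{10 s}}.
#'
#' @param k0 pre-exponential constant, per year (> 0).
#' @param s temperature slope, per C.
#' @return Object of class `exp_rate_law` with element `q10_implied`;
#'   callable via [rate_at_temperature()].
#' @examples
#' law <- exp_rate_law(0.2834, 0.0435)
#' rate_at_temperature(law, 40)  # ~ 1.61 per year
#' @export
exp_rate_law <- function(k0, s) {
  check_number(k0, "k0", lower = 0, allow_lower = FALSE)
  check_number(s, "s")
  structure(list(k0 = k0, s = s, q10_implied = exp(10 * s)),
            class = "exp_rate_law")
}

#' @rdname exp_rate_law
#' @param law an `exp_rate_law`.
#' @param t_c temperature, C (vectorised).
#' @export
rate_at_temperature <- function(law, t_c) {
  if (!inherits(law, "exp_rate_law"))
    stop_invalid("`law` must be an exp_rate_law")
  law$k0 * exp(law$s * t_c)
}

#' Temperature factor m(T)
#'
#' @param t_c temperature, C (vectorised); valid domain is 0 <= T <= T_m.
#' @param resp a [temperature_response()].
#' @param extrapolate allow evaluation above the optimum. The Q10 form is
#'   proposed only up to the optimum; above it real rates decline, so
#'   extrapolation must be requested explicitly.
#' @return m in (0, 1] over the valid domain.
#' @export
temperature_factor <- function(t_c, resp, extrapolate = FALSE) {
  if (!inherits(resp, "temperature_response"))
    stop_invalid("`resp` must be a temperature_response")
  check_numeric_vector(t_c, "t_c")
  if (!extrapolate && any(t_c > resp$t_opt))
    stop_invalid("temperature above the optimum ", resp$t_opt,
                 " C: the Q10 model is not valid there; set ",
                 "`extrapolate = TRUE` to force evaluation")
  resp$q10^((t_c - resp$t_opt) / 10)
}

#' Moisture factor f(W)
#'
#' @param w_rel relative moisture W/W_s in [0, 1] (vectorised); both endpoints
#'   map to 0 (air-dry and waterlogged anoxic limits).
#' @param resp a [moisture_response()].
#' @return f in [0, 1], exactly 1 at `w_opt`.
#' @export
moisture_factor <- function(w_rel, resp) {
  if (!inherits(resp, "moisture_response"))
    stop_invalid("`resp` must be a moisture_response")
  check_numeric_vector(w_rel, "w_rel")
  if (any(w_rel < 0 | w_rel > 1))
    stop_invalid("`w_rel` must lie in [0, 1]")
  wm <- resp$w_opt
  ifelse(w_rel <= 0 | w_rel >= 1, 0,
         (w_rel / wm)^resp$a * ((1 - w_rel) / (1 - wm))^resp$b)
}

#' Combined hydrothermal rate U = f(W) m(T) U_max
#'
#' @param t_c temperature, C.
#' @param w_rel relative moisture W/W_s.
#' @param t_resp a [temperature_response()].
#' @param m_resp a [moisture_response()].
#' @param u_max rate at the joint optimum; defaults to the `u_max` stored in
#'   either response object.
#' @param extrapolate passed to [temperature_factor()].
#' @return Rate in the units of `u_max`; the maximum over the domain is
#'   `u_max`, attained at (t_opt, w_opt).
#' @export
combined_rate <- function(t_c, w_rel, t_resp, m_resp, u_max = NULL,
                          extrapolate = FALSE) {
  if (is.null(u_max)) {
    u_max <- if (!is.na(m_resp$u_max)) m_resp$u_max else t_resp$u_max
    if (is.na(u_max))
      stop_invalid("`u_max` is neither supplied nor stored in a response")
  }
  temperature_factor(t_c, t_resp, extrapolate = extrapolate) *
    moisture_factor(w_rel, m_resp) * u_max
}

# ---- fitting ---------------------------------------------------------------

#' Fit the extremum moisture response
#'
#' Nonlinear least squares of \eqn{U = U_{max} f(W)} to (W/W_s, U) pairs. The
#' optimisation runs in (log a, log b, log u_max) to enforce positivity, then
#' refits once in natural scale at the optimum to obtain standard errors and
#' p-values. In normalized mode (default) rates are divided by their maximum
#' and only a, b are estimated, matching dimensionless response formulas.
#'
#' @param w_rel relative moisture values, must span both sides of the apparent
#'   maximum.
#' @param u rates, same length.
#' @param normalize if `TRUE` (default), rates are pre-scaled by their
#'   observed maximum and the fit runs on the dimensionless factor with a
#'   free scale near 1 (the observed maximum rarely falls exactly at the
#'   extremum), so residuals and the approximation error are on the
#'   normalized scale; if `FALSE`, fit the dimensional rates directly.
#' @return A [moisture_response()] with attributes `r_squared`,
#'   `approx_error` (root-mean-square residual of normalized rates, the
#'   standard error of approximation), `p_values`, `std_errors`, `fitted`
#'   and `formula` (the rendered model string).
#' @examples
#' w <- seq(0.1, 0.95, by = 0.05)
#' u <- 30 * moisture_factor(w, moisture_response(4.84, 2.35))
#' fit_moisture_response(w, u)
#' @export
fit_moisture_response <- function(w_rel, u, normalize = TRUE) {
  check_numeric_vector(w_rel, "w_rel")
  check_numeric_vector(u, "u", lower = 0)
  if (length(w_rel) != length(u))
    stop_invalid("`w_rel` and `u` must have equal length")
  if (length(u) < 5L)
    stop_invalid("at least 5 points are required")
  if (any(w_rel <= 0 | w_rel > 1))
    stop_invalid("`w_rel` must lie in (0, 1]")
  imax <- which.max(u)
  if (imax == 1L || imax == length(u)) {
    ord <- order(w_rel)
    if (which.max(u[ord]) %in% c(1L, length(u)))
      stop_fit("all points lie on one side of the apparent maximum: ",
               "the extremum model is ill-posed for these data")
  }

  # deterministic start: empirical argmax, a0 = 2, b0 from the extremum identity
  w0 <- w_rel[imax]
  a0 <- 2
  b0 <- a0 * (1 - w0) / w0
  umax0 <- max(u)

  f_model <- function(w, a, b) {
    wm <- a / (a + b)
    ifelse(w >= 1, 0, (w / wm)^a * ((1 - w) / (1 - wm))^b)
  }
  # normalized mode: pre-scale by the observed maximum and co-fit a scale
  # near 1 (the sampled maximum rarely falls exactly on the extremum)
  y <- if (normalize) u / umax0 else u
  lu0 <- if (normalize) 0 else log(umax0)
  dat <- data.frame(w = w_rel, y = y)

  fit <- tryCatch(
    nlslm_retry(y ~ exp(lu) * f_model(w, exp(la), exp(lb)),
                data = dat,
                start = list(la = log(a0), lb = log(b0), lu = lu0)),
    error = function(e)
      stop_fit("moisture-response fit did not converge: ",
               conditionMessage(e)))

  cf <- stats::coef(fit)
  a_hat <- exp(unname(cf["la"]))
  b_hat <- exp(unname(cf["lb"]))
  u_hat <- exp(unname(cf["lu"])) * (if (normalize) umax0 else 1)

  # natural-scale refit at the optimum for reporting (SEs, p-values)
  nat <- tryCatch(
    minpack.lm::nlsLM(y ~ umax * f_model(w, a, b), data = dat,
                      start = list(a = a_hat, b = b_hat,
                                   umax = exp(unname(cf["lu"]))),
                      lower = c(1e-8, 1e-8, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) fit)
  sm <- summary(nat)$coefficients

  fitted_u <- u_hat * f_model(w_rel, a_hat, b_hat)
  resp <- moisture_response(a_hat, b_hat, u_max = u_hat)
  attr(resp, "r_squared") <- r_squared(u, fitted_u)
  attr(resp, "approx_error") <- sqrt(mean(((u - fitted_u) / u_hat)^2))
  attr(resp, "std_errors") <- sm[, "Std. Error"]
  attr(resp, "p_values") <- sm[, "Pr(>|t|)"]
  attr(resp, "fitted") <- fitted_u
  attr(resp, "formula") <- format(resp)
  resp
}

#' Fit the exponential temperature law for k
#'
#' Least squares of \eqn{k = k_0 e^{sT}} to (temperature, decay constant)
#' pairs, initialised from the log-linear regression.
#'
#' @param temp_c temperatures, C (at least 3 distinct values).
#' @param k decay constants, per year (> 0).
#' @return An [exp_rate_law()] with attributes `r_squared` and `fitted`.
#' @export
fit_rate_temperature <- function(temp_c, k) {
  check_numeric_vector(temp_c, "temp_c")
  check_numeric_vector(k, "k", lower = 0)
  if (length(temp_c) != length(k))
    stop_invalid("`temp_c` and `k` must have equal length")
  if (length(unique(temp_c)) < 3L)
    stop_invalid("at least 3 distinct temperature levels are required")
  if (any(k <= 0))
    stop_invalid("decay constants must be positive")
  start <- stats::coef(stats::lm(log(k) ~ temp_c))
  dat <- data.frame(t = temp_c, k = k)
  fit <- tryCatch(
    minpack.lm::nlsLM(k ~ k0 * exp(s * t), data = dat,
                      start = list(k0 = exp(unname(start[1])),
                                   s = unname(start[2])),
                      lower = c(1e-12, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop_fit("k(T) fit did not converge: ",
                                 conditionMessage(e)))
  cf <- stats::coef(fit)
  law <- exp_rate_law(unname(cf["k0"]), unname(cf["s"]))
  fitted_k <- rate_at_temperature(law, temp_c)
  attr(law, "r_squared") <- r_squared(k, fitted_k)
  attr(law, "fitted") <- fitted_k
  law
}

#' Fit the joint hydrothermal response surface
#'
#' Single least-squares problem for \eqn{U = U_{max} f(W) m(T)} over a
#' (temperature, moisture) grid. Q10 is fixed at 2 by default (the field
#' average) or co-fitted.
#'
#' @param temp_c,w_rel,u grid columns of equal length.
#' @param t_opt optimum temperature, C (fixed).
#' @param q10 fixed Q10 value, or `NULL` to co-fit it.
#' @return List with `moisture_response`, `temperature_response`, `u_max`,
#'   `r_squared` and `fitted`.
#' @export
fit_response_surface <- function(temp_c, w_rel, u, t_opt = 30, q10 = 2) {
  check_numeric_vector(temp_c, "temp_c")
  check_numeric_vector(w_rel, "w_rel")
  check_numeric_vector(u, "u", lower = 0)
  n <- length(u)
  if (length(temp_c) != n || length(w_rel) != n)
    stop_invalid("grid columns must have equal length")
  if (n < 6L) stop_invalid("at least 6 grid points are required")
  fit_q10 <- is.null(q10)

  f_model <- function(w, a, b) {
    wm <- a / (a + b)
    ifelse(w >= 1, 0, (w / wm)^a * ((1 - w) / (1 - wm))^b)
  }
  imax <- which.max(u)
  w0 <- w_rel[imax]
  start <- list(la = log(2), lb = log(2 * (1 - w0) / w0), lu = log(max(u)))
  dat <- data.frame(t = temp_c, w = w_rel, u = u)
  fit <- tryCatch({
    if (fit_q10)
      nlslm_retry(
        u ~ exp(lu) * f_model(w, exp(la), exp(lb)) *
          exp(lq)^((t - t_opt) / 10),
        data = dat, start = c(start, lq = log(2)))
    else
      nlslm_retry(
        u ~ exp(lu) * f_model(w, exp(la), exp(lb)) * q10^((t - t_opt) / 10),
        data = dat, start = start)
  }, error = function(e)
    stop_fit("response-surface fit did not converge: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  q10_hat <- if (fit_q10) exp(unname(cf["lq"])) else q10
  u_max <- exp(unname(cf["lu"]))
  m_resp <- moisture_response(exp(unname(cf["la"])), exp(unname(cf["lb"])),
                              u_max = u_max)
  t_resp <- temperature_response(q10 = q10_hat, t_opt = t_opt, u_max = u_max)
  fitted_u <- combined_rate(temp_c, w_rel, t_resp, m_resp,
                            extrapolate = TRUE)
  list(moisture_response = m_resp, temperature_response = t_resp,
       u_max = u_max, r_squared = r_squared(u, fitted_u), fitted = fitted_u)
}

#' Read a hydrothermal response grid
#'
#' Delimited text with header `temp_c,w_rel,u_m`.
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
read_response_grid <- function(path) {
  load_dataset(path, c(temp_c = "numeric", w_rel = "numeric",
                       u_m = "numeric"))
}

#' Write a moisture-response fit report as JSON
#'
#' @param resp a fitted [moisture_response()] (from [fit_moisture_response()]).
#' @param path output path.
#' @export
write_response_report <- function(resp, path) {
  if (!inherits(resp, "moisture_response"))
    stop_invalid("`resp` must be a moisture_response")
  report <- list(a = resp$a, b = resp$b, w_opt = resp$w_opt,
                 u_max = resp$u_max,
                 r_squared = attr(resp, "r_squared"),
                 approx_error = attr(resp, "approx_error"),
                 p_values = as.list(attr(resp, "p_values")),
                 formula = attr(resp, "formula"))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
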