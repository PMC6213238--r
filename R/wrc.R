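#' van Genuchten water-retention parameters
#'
#' The water-retention curve is approximated by the standard
#' Mualem-constrained van Genuchten form
#' \deqn{\theta(\psi) = \theta_r + \frac{\theta_s - \theta_r}
#'   {[1 + (\alpha\psi)^n]^m}, \quad m = 1 - 1/n,}
#' with the potential \eqn{\psi} as an equivalent pressure in kPa and water
#' contents in percent by mass.
#'
#' @param theta_r residual water content, percent, in [0, theta_s).
#' @param theta_s saturated water content, percent, in (theta_r, 100].
#' @param alpha inverse-pressure scale, kPa^-1 (> 0).
#' @param n_shape shape exponent (> 1); `m_shape = 1 - 1/n_shape` is derived.
#' @return Object of class `vg_params`.
#' @export
vg_params <- function(theta_r, theta_s, alpha, n_shape) {
  check_number(theta_r, "theta_r", lower = 0)
  check_number(theta_s, "theta_s", lower = 0, upper = 100,
               allow_lower = FALSE)
  if (theta_r >= theta_s)
    stop_invalid("`theta_r` must be below `theta_s`")
  check_number(alpha, "alpha", lower = 0, allow_lower = FALSE)
  check_number(n_shape, "n_shape", lower = 1, allow_lower = FALSE)
  structure(list(theta_r = theta_r, theta_s = theta_s, alpha = alpha,
                 n_shape = n_shape, m_shape = 1 - 1 / n_shape),
            class = "vg_params")
}

#' Water content at a given pressure
#'
#' @param pressure equivalent pressure (water-retention energy), kPa (>= 0,
#'   vectorised). Zero pressure returns `theta_s`.
#' @param params a [vg_params()].
#' @return Water content, percent; strictly non-increasing in pressure and
#'   bounded in [theta_r, theta_s].
#' @export
vg_water_content <- function(pressure, params) {
  if (!inherits(params, "vg_params"))
    stop_invalid("`params` must be vg_params")
  check_numeric_vector(pressure, "pressure", lower = 0)
  params$theta_r + (params$theta_s - params$theta_r) /
    (1 + (params$alpha * pressure)^params$n_shape)^params$m_shape
}

#' Water-retention dataset
#'
#' @param pressure pressures, kPa (>= 0; centrifugation covers roughly
#'   0 to 800-1000 kPa).
#' @param water_content water contents, percent by mass.
#' @param tolerance allowed non-monotonicity (percent points) before a
#'   warning is raised.
#' @return Object of class `retention_dataset` (data.frame with columns
#'   `pressure_kpa`, `theta_percent`, sorted by pressure).
#' @export
retention_dataset <- function(pressure, water_content, tolerance = 2) {
  check_numeric_vector(pressure, "pressure", lower = 0)
  check_numeric_vector(water_content, "water_content", lower = 0)
  if (length(pressure) != length(water_content))
    stop_invalid("`pressure` and `water_content` must have equal length")
  ord <- order(pressure)
  p <- pressure[ord]
  th <- water_content[ord]
  if (any(diff(th) > tolerance))
    warning("water content increases with pressure beyond the noise ",
            "tolerance", call. = FALSE)
  structure(data.frame(pressure_kpa = p, theta_percent = th),
            class = c("retention_dataset", "data.frame"))
}

#' Fit the van Genuchten retention model
#'
#' Constrained nonlinear least squares of the retention curve;
#' \eqn{\theta_s} is initialised from the lowest-pressure point,
#' \eqn{\alpha} from the pressure at the curve midpoint, and the shape
#' exponent is kept above 1 throughout.
#'
#' @param data a [retention_dataset()] with at least 5 pressure levels,
#'   including a near-zero pressure.
#' @return A [vg_params()] with attributes `r_squared` and `fitted`.
#' @export
fit_wrc <- function(data) {
  if (!inherits(data, "retention_dataset"))
    stop_invalid("`data` must be a retention_dataset")
  p <- data$pressure_kpa
  th <- data$theta_percent
  if (length(p) < 5L)
    stop_invalid("at least 5 pressure levels are required")
  if (min(p) > 10)
    stop_invalid("a near-zero pressure point (<= 10 kPa) is required to ",
                 "anchor theta_s")
  if (diff(range(th)) < 1e-3 * max(th, 1))
    stop_fit("degenerate flat retention curve: the model is ill-posed")

  theta_s0 <- th[which.min(p)]
  theta_r0 <- max(min(th) * 0.5, 0)
  mid <- (theta_s0 + theta_r0) / 2
  p_mid <- p[which.min(abs(th - mid))]
  alpha0 <- if (p_mid > 0) 1 / p_mid else 0.1
  dat <- data.frame(p = p, th = th)
  fit <- tryCatch(
    nlslm_retry(
      th ~ tr + (ts - tr) / (1 + (al * p)^nn)^(1 - 1 / nn),
      data = dat,
      start = list(tr = theta_r0, ts = theta_s0, al = alpha0, nn = 1.5),
      lower = c(0, 1e-6, 1e-8, 1 + 1e-6),
      upper = c(100, 100, Inf, 20)),
    error = function(e) stop_fit("retention-curve fit did not converge: ",
                                 conditionMessage(e)))
  cf <- stats::coef(fit)
  params <- vg_params(unname(cf["tr"]), unname(cf["ts"]), unname(cf["al"]),
                      unname(cf["nn"]))
  fitted_th <- vg_water_content(p, params)
  attr(params, "r_squared") <- r_squared(th, fitted_th)
  attr(params, "fitted") <- fitted_th
  params
}

#' Capacity metrics of a fitted retention curve
#'
#' Total moisture capacity (the saturated water content) and field moisture
#' capacity, read from the curve at a conventional water potential. No
#' universal potential exists for field capacity; the 33 kPa default is the
#' package's convention and should be set explicitly when a different
#' criterion (e.g. a secant-based one) is in use.
#'
#' @param params a [vg_params()].
#' @param field_capacity_pressure potential for field capacity, kPa (> 0).
#' @return List with `total_capacity` (= theta_s, percent) and
#'   `field_capacity` (percent at the supplied potential).
#' @export
capacity_metrics <- function(params, field_capacity_pressure = 33) {
  if (!inherits(params, "vg_params"))
    stop_invalid("`params` must be vg_params")
  check_number(field_capacity_pressure, "field_capacity_pressure", lower = 0,
               allow_lower = FALSE)
  list(total_capacity = params$theta_s,
       field_capacity = vg_water_content(field_capacity_pressure, params))
}

#' Read a water-retention dataset
#'
#' Delimited text with header `pressure_kpa,theta_percent`.
#'
#' @param path file path.
#' @return A [retention_dataset()].
#' @export
read_wrc <- function(path) {
  d <- load_dataset(path, c(pressure_kpa = "numeric",
                            theta_percent = "numeric"))
  retention_dataset(d$pressure_kpa, d$theta_percent)
}

#' Write fitted retention parameters as JSON
#'
#' @param params a [vg_params()].
#' @param path output path.
#' @export
write_vg_params <- function(params, path) {
  if (!inherits(params, "vg_params"))
    stop_invalid("`params` must be vg_params")
  out <- c(unclass(params), list(r_squared = attr(params, "r_squared")))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
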