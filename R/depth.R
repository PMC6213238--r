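#' Exponential depth-attenuation profile of biological activity
#'
#' Soil respiration declines with depth as
#' \deqn{U_m(h) = U_0 + a e^{-bh},}
#' where U_0 is the deep asymptote, a the surface-excess amplitude and b
#' (cm^-1) the attenuation coefficient; for most mineral soils
#' 0.1 <= b <= 1 cm^-1.
#'
#' @param u_inf asymptotic activity U_0 at depth, mg kg^-1 h^-1 (>= 0).
#' @param amplitude surface-excess amplitude a, mg kg^-1 h^-1 (> 0).
#' @param attenuation decline coefficient b, cm^-1 (> 0).
#' @return Object of class `depth_profile`.
#' @export
depth_profile <- function(u_inf, amplitude, attenuation) {
  check_number(u_inf, "u_inf", lower = 0)
  check_number(amplitude, "amplitude", lower = 0, allow_lower = FALSE)
  check_number(attenuation, "attenuation", lower = 0, allow_lower = FALSE)
  structure(list(u_inf = u_inf, amplitude = amplitude,
                 attenuation = attenuation),
            class = "depth_profile")
}

#' Biological activity at depth
#'
#' @param h depth, cm (>= 0, vectorised).
#' @param profile a [depth_profile()].
#' @return Activity U_m(h), mg kg^-1 h^-1.
#' @export
depth_activity <- function(h, profile) {
  if (!inherits(profile, "depth_profile"))
    stop_invalid("`profile` must be a depth_profile")
  check_numeric_vector(h, "h", lower = 0)
  profile$u_inf + profile$amplitude * exp(-profile$attenuation * h)
}

#' Fit the exponential depth profile
#'
#' Nonlinear least squares of \eqn{U_m(h) = U_0 + a e^{-bh}} with the
#' asymptote constrained non-negative. Requires at least 4 depths including
#' near-surface and deep points; a profile that increases with depth beyond
#' noise triggers a warning.
#'
#' @param h depths, cm.
#' @param u activities, mg kg^-1 h^-1.
#' @return A [depth_profile()] with attributes `r_squared` and `fitted`.
#' @export
fit_depth_profile <- function(h, u) {
  check_numeric_vector(h, "h", lower = 0)
  check_numeric_vector(u, "u", lower = 0)
  if (length(h) != length(u)) stop_invalid("`h` and `u` have unequal length")
  if (length(h) < 4L) stop_invalid("at least 4 depths are required")
  ord <- order(h)
  if (stats::cor(h, u) > 0)
    warning("activity increases with depth beyond noise: the exponential ",
            "attenuation model may be inappropriate", call. = FALSE)

  u0_0 <- max(min(u), 0)
  a0 <- max(max(u) - u0_0, 1e-8)
  # slope of log surface-excess as a starting attenuation
  excess <- u - 0.9 * u0_0
  pos <- excess > 0
  b0 <- if (sum(pos) >= 2)
    max(-unname(stats::coef(stats::lm(log(excess[pos]) ~ h[pos]))[2]), 1e-3)
  else 0.3
  dat <- data.frame(h = h, u = u)
  fit <- tryCatch(
    nlslm_retry(u ~ u0 + a * exp(-b * h), data = dat,
                start = list(u0 = u0_0, a = a0, b = b0),
                lower = c(0, 1e-12, 1e-8)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # an asymptote indistinguishable from zero makes the three-parameter
    # gradient numerically singular; refit the pure-exponential profile
    fit <- tryCatch(
      nlslm_retry(u ~ a * exp(-b * h), data = dat,
                  start = list(a = u0_0 + a0, b = b0),
                  lower = c(1e-12, 1e-8)),
      error = function(e) stop_fit("depth-profile fit did not converge: ",
                                   conditionMessage(e)))
  }
  cf <- stats::coef(fit)
  u0_hat <- if ("u0" %in% names(cf)) unname(cf["u0"]) else 0
  prof <- depth_profile(u0_hat, unname(cf["a"]), unname(cf["b"]))
  fitted_u <- depth_activity(h, prof)
  attr(prof, "r_squared") <- r_squared(u, fitted_u)
  attr(prof, "fitted") <- fitted_u
  prof
}

#' Characteristic depths of biological activity
#'
#' By analogy with the characteristic decay times, the depths above which
#' 50\% and 95\% of the surface-excess activity is concentrated:
#' \eqn{H_{0.5} = \ln 2 / b}, \eqn{H_{0.95} = 3 / b}.
#'
#' @param attenuation coefficient b, cm^-1 (> 0).
#' @return Named vector `c(h_half, h_95)` in cm.
#' @examples
#' characteristic_depths(0.1)  # 6.93 and 30 cm
#' @export
characteristic_depths <- function(attenuation) {
  check_number(attenuation, "attenuation", lower = 0, allow_lower = FALSE)
  c(h_half = log(2) / attenuation, h_95 = 3 / attenuation)
}

#' Burial depth for a target reduction in biodegradation
#'
#' Depth at which a conditioner must be placed so that its biodegradation is
#' reduced n-fold relative to the surface: \eqn{H = \ln(n)/b}. The
#' attenuation coefficient is supplied directly or derived from the active
#' biogenic layer via \eqn{b = 3 / H_{0.95}}. The exponential form ignores
#' the deep asymptote U_0 (it attenuates the surface-excess activity);
#' [burial_depth_floored()] accounts for a nonzero floor.
#'
#' @param n reduction factor (>= 1, vectorised).
#' @param attenuation coefficient b, cm^-1; or
#' @param active_layer active-layer thickness H_0.95, cm. Supply exactly one.
#' @return Burial depth H, cm; satisfies `exp(b * H) == n` exactly.
#' @examples
#' burial_depth(4, attenuation = 0.35)  # 3.96 cm, prints as 4 cm
#' @export
burial_depth <- function(n, attenuation = NULL, active_layer = NULL) {
  check_numeric_vector(n, "n", lower = 1)
  if (is.null(attenuation) == is.null(active_layer))
    stop_invalid("supply exactly one of `attenuation` or `active_layer`")
  b <- if (!is.null(attenuation)) {
    check_number(attenuation, "attenuation", lower = 0, allow_lower = FALSE)
    attenuation
  } else {
    check_number(active_layer, "active_layer", lower = 0, allow_lower = FALSE)
    3 / active_layer
  }
  log(n) / b
}

#' @rdname burial_depth
#' @param profile a [depth_profile()]; solves
#'   \eqn{U_0 + a e^{-bH} = (U_0 + a)/n}, which has no solution once the
#'   target activity falls below the deep asymptote.
#' @export
burial_depth_floored <- function(n, profile) {
  check_numeric_vector(n, "n", lower = 1)
  if (!inherits(profile, "depth_profile"))
    stop_invalid("`profile` must be a depth_profile")
  target <- (profile$u_inf + profile$amplitude) / n
  if (any(target <= profile$u_inf))
    stop_invalid("reduction factor unattainable: target activity at or ",
                 "below the deep asymptote U_0")
  -log((target - profile$u_inf) / profile$amplitude) / profile$attenuation
}

#' Burial-depth nomograph table
#'
#' Dense analytic table of burial depths over a range of attenuation
#' coefficients (`mode = "attenuation"`, default b in [0.1, 1] cm^-1) or
#' active-layer thicknesses (`mode = "active_layer"`, default H_0.95 in
#' [6, 30] cm), one curve per reduction factor. Values are exact evaluations
#' of \eqn{H = \ln(n)/b}; reading a published nomograph graphically can
#' differ by 1-2 cm from the analytic value.
#'
#' @param mode `"attenuation"` or `"active_layer"`.
#' @param x_range length-2 range of the abscissa (b in cm^-1, or H_0.95 in
#'   cm).
#' @param reduction_factors reduction factors n, all > 1; the default follows
#'   the customary nomograph line set.
#' @param n_points number of abscissa points (>= 2).
#' @return data.frame in long format with columns `x` (abscissa), `n`
#'   (reduction factor), `depth_cm`; attribute `mode`.
#' @export
nomograph_table <- function(mode = c("attenuation", "active_layer"),
                            x_range = NULL,
                            reduction_factors = c(2, 3, 4, 6, 8, 16, 32),
                            n_points = 50) {
  mode <- match.arg(mode)
  check_numeric_vector(reduction_factors, "reduction_factors")
  if (any(reduction_factors <= 1))
    stop_invalid("all reduction factors must exceed 1")
  if (is.null(x_range))
    x_range <- if (mode == "attenuation") c(0.1, 1) else c(6, 30)
  check_numeric_vector(x_range, "x_range", lower = 0)
  if (length(x_range) != 2L || diff(x_range) <= 0 || x_range[1] <= 0)
    stop_invalid("`x_range` must be an increasing positive length-2 range")
  if (n_points < 2L) stop_invalid("`n_points` must be at least 2")
  x <- seq(x_range[1], x_range[2], length.out = n_points)
  grid <- expand.grid(x = x, n = sort(reduction_factors))
  grid$depth_cm <- if (mode == "attenuation") log(grid$n) / grid$x
  else log(grid$n) * grid$x / 3
  structure(grid, mode = mode,
            class = c("nomograph_table", "data.frame"))
}

#' Plot a nomograph
#'
#' One burial-depth curve per reduction factor, base graphics.
#'
#' @param x a [nomograph_table()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.nomograph_table <- function(x, ...) {
  wide <- stats::reshape(as.data.frame(x), idvar = "x", timevar = "n",
                         direction = "wide")
  xlab <- if (attr(x, "mode") == "attenuation")
    "attenuation b (1/cm)" else "active layer H0.95 (cm)"
  graphics::matplot(wide$x, as.matrix(wide[, -1]), type = "l", lty = 1,
                    xlab = xlab, ylab = "burial depth H (cm)", ...)
  graphics::legend("topright", legend = paste0("n = ", sort(unique(x$n))),
                   lty = 1, col = seq_along(unique(x$n)), bty = "n")
  invisible(x)
}

#' Write a nomograph table as delimited text
#'
#' @param table a [nomograph_table()].
#' @param path output path.
#' @export
write_nomograph <- function(table, path) {
  if (!inherits(table, "nomograph_table"))
    stop_invalid("`table` must be a nomograph_table")
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
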