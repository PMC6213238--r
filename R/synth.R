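#' Synthetic hydrothermal response grid
#'
#' Generates a (temperature, relative moisture, rate) table from a known
#' hydrothermal response surface plus independent additive Gaussian noise.
#' Emulates laboratory incubation grids measured across moisture and
#' temperature levels; the generating parameters are embedded as the `truth`
#' attribute so round-trip tests never re-derive them.
#'
#' @param m_resp a [moisture_response()] (must carry `u_max` or supply
#'   `u_max`).
#' @param t_resp a [temperature_response()].
#' @param u_max rate at the optimum, mg kg^-1 h^-1.
#' @param w_grid relative moisture grid in (0, 1).
#' @param t_grid temperature grid, C, within [0, t_opt].
#' @param noise_sd absolute noise standard deviation (same unit as the rate);
#'   see `relative`.
#' @param relative if `TRUE`, `noise_sd` is interpreted as a fraction of
#'   `u_max` (heteroscedastic scenarios use `relative = TRUE` with a
#'   per-point scale).
#' @param seed integer seed; identical seed and configuration give identical
#'   output. `NULL` leaves the RNG stream untouched.
#' @return data.frame with columns `temp_c`, `w_rel`, `u_m`; attribute
#'   `truth` holds the generator inputs.
#' @export
gen_response_grid <- function(m_resp, t_resp, u_max = m_resp$u_max,
                              w_grid = seq(0.1, 0.95, by = 0.05),
                              t_grid = c(5, 10, 15, 20, 25, 30),
                              noise_sd = 0, relative = FALSE, seed = NULL) {
  if (!inherits(m_resp, "moisture_response") ||
      !inherits(t_resp, "temperature_response"))
    stop_invalid("response objects of the proper classes are required")
  if (is.na(u_max)) stop_invalid("`u_max` is required")
  check_number(noise_sd, "noise_sd", lower = 0)
  grid <- expand.grid(temp_c = t_grid, w_rel = w_grid)
  u <- combined_rate(grid$temp_c, grid$w_rel, t_resp, m_resp, u_max = u_max)
  sd_abs <- if (relative) noise_sd * u_max else noise_sd
  u_obs <- with_seed(seed, u + stats::rnorm(length(u), sd = sd_abs))
  out <- data.frame(temp_c = grid$temp_c, w_rel = grid$w_rel,
                    u_m = pmax(u_obs, 0))
  attr(out, "truth") <- list(a = m_resp$a, b = m_resp$b,
                             w_opt = m_resp$w_opt, q10 = t_resp$q10,
                             t_opt = t_resp$t_opt, u_max = u_max,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Synthetic mass-loss (decomposition) series
#'
#' Percent-retained series from first-order decay with known k, optionally
#' modulated by a seasonal temperature cycle (the decay constant then varies
#' as \eqn{k(t) = k_{max} m(T(t))} with a Q10 temperature factor and the
#' supplied annual forcing, integrated exactly piecewise). Additive Gaussian
#' noise is applied to every point after t = 0; the start value is exactly
#' 100 since the retained fraction is 100 percent by definition at t = 0.
#'
#' @param k decay constant, per year (seasonal mode: the annual-mean constant
#'   is rescaled so long-run loss still follows `k`).
#' @param times sampling times, years, strictly increasing starting at 0.
#' @param noise_sd Gaussian noise on percent retained (absolute, percent
#'   points).
#' @param seed integer seed or `NULL`.
#' @param seasonal logical; modulate k by an annual temperature cycle.
#' @param forcing annual temperature [sinusoid_forcing()] used when
#'   `seasonal = TRUE`; default [moscow_like_forcing()].
#' @param q10 temperature coefficient of the modulation.
#' @return A [mass_loss_series()] with attribute `truth`.
#' @export
gen_decay_series <- function(k, times = seq(0, 2, by = 0.25), noise_sd = 0,
                             seed = NULL, seasonal = FALSE,
                             forcing = moscow_like_forcing(), q10 = 2) {
  check_number(k, "k", lower = 0)
  check_numeric_vector(times, "times", lower = 0)
  if (times[1] != 0) stop_invalid("`times` must start at 0")
  if (is.unsorted(times, strictly = TRUE))
    stop_invalid("`times` must be strictly increasing")
  check_number(noise_sd, "noise_sd", lower = 0)
  if (!seasonal) {
    d <- decay_curve(100, k, times)
  } else {
    # hourly piecewise-exact integral of k * m(T(t)), normalised so the
    # annual mean modulation is 1 and the long-run constant stays k
    t_resp <- temperature_response(q10 = q10, t_opt = 30)
    t_h <- seq(0, max(times) * HOURS_PER_YEAR, by = 24)
    mod <- temperature_factor(evaluate_forcing(forcing, t_h), t_resp,
                              extrapolate = TRUE)
    mod <- mod / mean(mod)
    cum <- c(0, cumsum((mod[-1] + mod[-length(mod)]) / 2 * 24)) /
      HOURS_PER_YEAR
    d <- 100 * exp(-k * stats::approx(t_h, cum, xout = times *
                                        HOURS_PER_YEAR)$y)
  }
  obs <- with_seed(seed, d + c(0, stats::rnorm(length(times) - 1,
                                               sd = noise_sd)))
  obs <- pmax(obs, 0)
  obs[1] <- 100
  out <- mass_loss_series(times, obs, kind = "mass")
  attr(out, "truth") <- list(k = k, noise_sd = noise_sd, seed = seed,
                             seasonal = seasonal, q10 = q10)
  out
}

#' Synthetic depth profile of biological activity
#'
#' Exponential depth attenuation with known parameters plus Gaussian noise.
#'
#' @param profile a [depth_profile()] holding the ground truth.
#' @param depths sampling depths, cm (>= 0).
#' @param noise_sd absolute Gaussian noise, mg kg^-1 h^-1; or a fraction of
#'   the surface activity when `relative = TRUE`.
#' @param relative interpret `noise_sd` relatively.
#' @param seed integer seed or `NULL`.
#' @return data.frame with columns `h`, `u_m`; attribute `truth`.
#' @export
gen_depth_profile <- function(profile, depths = c(0, 2, 5, 10, 20, 40),
                              noise_sd = 0, relative = FALSE, seed = NULL) {
  if (!inherits(profile, "depth_profile"))
    stop_invalid("`profile` must be a depth_profile")
  check_numeric_vector(depths, "depths", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  u <- depth_activity(depths, profile)
  sd_abs <- if (relative) noise_sd * (profile$u_inf + profile$amplitude)
  else noise_sd
  u_obs <- with_seed(seed, u + stats::rnorm(length(u), sd = sd_abs))
  out <- data.frame(h = depths, u_m = pmax(u_obs, 0))
  attr(out, "truth") <- c(unclass(profile),
                          list(noise_sd = noise_sd, seed = seed))
  out
}

#' Synthetic water-retention dataset
#'
#' van Genuchten curve with known parameters plus Gaussian noise over a
#' centrifugation-style pressure grid (0 to about 1000 kPa).
#'
#' @param params a [vg_params()] holding the ground truth.
#' @param pressures pressure grid, kPa, within [0, 1000].
#' @param noise_sd Gaussian noise on water content, percent points.
#' @param clip_monotone force the noisy curve non-increasing (cumulative
#'   minimum over increasing pressure).
#' @param seed integer seed or `NULL`.
#' @return A [retention_dataset()] with attribute `truth`.
#' @export
gen_wrc_dataset <- function(params,
                            pressures = c(0, 1, 3, 6, 10, 20, 33, 60, 100,
                                          200, 400, 700, 1000),
                            noise_sd = 0, clip_monotone = FALSE,
                            seed = NULL) {
  if (!inherits(params, "vg_params"))
    stop_invalid("`params` must be vg_params")
  check_numeric_vector(pressures, "pressures", lower = 0)
  if (any(pressures > 1000))
    stop_invalid("pressure grid must stay within [0, 1000] kPa")
  check_number(noise_sd, "noise_sd", lower = 0)
  pressures <- sort(pressures)
  th <- vg_water_content(pressures, params)
  th_obs <- with_seed(seed, th + stats::rnorm(length(th), sd = noise_sd))
  th_obs <- pmax(th_obs, 0)
  if (clip_monotone) th_obs <- cummin(th_obs)
  out <- suppressWarnings(retention_dataset(pressures, th_obs))
  attr(out, "truth") <- c(unclass(params),
                          list(noise_sd = noise_sd, seed = seed))
  out
}

#' Temperate annual temperature cycle (synthetic)
#'
#' A synthetic stand-in for an unpublished humid-temperate monitoring series:
#' an annual sinusoid with mean 6 C and amplitude 14 C (winter minimum about
#' -8 C in mid-January, summer maximum about 20 C), period one year in hours.
#' It emulates the seasonal regime of a city like Moscow and is clearly not
#' observational data.
#'
#' @param mean annual mean temperature, C.
#' @param amplitude seasonal amplitude, C.
#' @return A [sinusoid_forcing()] with period 8760 h, phased so the minimum
#'   falls in mid-January.
#' @export
moscow_like_forcing <- function(mean = 6, amplitude = 14) {
  # phase: minimum near t = 360 h (day 15) => sin(...) = -1 there
  sinusoid_forcing(mean, amplitude, HOURS_PER_YEAR,
                   phase = -pi / 2 - 2 * pi * 360 / HOURS_PER_YEAR)
}
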