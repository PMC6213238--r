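test_that("sinusoid forcing evaluates the diurnal law", {
  f <- arid_forcing()
  # whenever the sine term vanishes the forcing sits at its mean
  t0 <- (2 * pi - 4.18) * 23.85 / (2 * pi)
  expect_equal(evaluate_forcing(f, t0), 38.14)
  expect_equal(evaluate_forcing(f, t0 + 23.85), 38.14)
  expect_equal(range(evaluate_forcing(f, seq(0, 23.85, by = 0.01))),
               c(38.14 - 4.45, 38.14 + 4.45), tolerance = 1e-4)
  flat <- sinusoid_forcing(10, 0, 24)
  expect_equal(evaluate_forcing(flat, c(0, 7, 100)), rep(10, 3))
})

test_that("tabulated forcing interpolates inside its range only", {
  lin <- tabulated_forcing(c(0, 10), c(0, 20), interpolation = "linear")
  expect_equal(evaluate_forcing(lin, 5), 10)
  expect_error(evaluate_forcing(lin, 11), class = "soildeg_invalid_input")
  # monotone spline is shape-preserving on monotone data: no overshoot
  tab <- tabulated_forcing(c(0, 5, 10, 20, 30), c(0, 1, 9, 10, 12))
  v <- evaluate_forcing(tab, seq(0, 30, by = 0.05))
  expect_gte(min(v), 0)
  expect_lte(max(v), 12)
  expect_true(all(diff(v) >= 0))
  expect_equal(evaluate_forcing(tab, c(0, 5, 10, 20, 30)),
               c(0, 1, 9, 10, 12))
  expect_error(tabulated_forcing(c(0, 0, 1), c(1, 2, 3)),
               class = "soildeg_invalid_input")
})

test_that("constant forcing reduces the simulation to the closed form", {
  law <- exp_rate_law(0.2834, 0.0435)
  m <- dynamic_decay_model(c0 = 100,
                           temperature_forcing = sinusoid_forcing(30, 0, 24),
                           rate_law = law)
  traj <- simulate_decay(m, 8760)
  k <- rate_at_temperature(law, 30)
  expect_equal(traj$c[nrow(traj)], 100 * exp(-k), tolerance = 1e-6)
  expect_equal(unique(round(traj$k_per_year, 10)), round(k, 10))
})

test_that("adaptive and piecewise-exact integrators agree under forcing", {
  m <- dynamic_decay_model(c0 = 0.1, temperature_forcing = arid_forcing(),
                           rate_law = exp_rate_law(0.2834, 0.0435))
  a <- total_loss_percent(simulate_decay(m, 580))
  b <- total_loss_percent(simulate_decay_stepwise(m, 580, step_h = 0.5))
  expect_equal(a, b, tolerance = 1e-4)
})

test_that("loss fraction is independent of the initial dose", {
  for (c0 in c(0.1, 0.2)) {
    m <- dynamic_decay_model(c0 = c0, temperature_forcing = arid_forcing(),
                             rate_law = exp_rate_law(0.2834, 0.0435))
    loss <- total_loss_percent(simulate_decay(m, 2160))
    if (c0 == 0.1) loss_ref <- loss
    expect_equal(loss, loss_ref, tolerance = 1e-9)
  }
})

test_that("long-horizon mean rate converges to the Bessel closed form", {
  law <- exp_rate_law(0.2834, 0.0435)
  f <- arid_forcing()
  k_bar <- mean_rate_sinusoid(law, f)
  expect_equal(k_bar, 0.2834 * exp(0.0435 * 38.14) *
                 besselI(0.0435 * 4.45, 0))
  # effective rate from a many-cycle simulation approaches the closed form
  m <- dynamic_decay_model(c0 = 1, temperature_forcing = f, rate_law = law)
  horizon <- 200 * 23.85
  traj <- simulate_decay(m, horizon, n_out = 1000)
  k_eff <- -log(traj$c[nrow(traj)]) / (horizon / 8760)
  expect_equal(k_eff, k_bar, tolerance = 1e-4)
})

test_that("trajectory composition matches a single integration", {
  law <- exp_rate_law(0.2834, 0.0435)
  f <- arid_forcing()
  m <- dynamic_decay_model(c0 = 100, temperature_forcing = f, rate_law = law)
  full <- simulate_decay(m, 1000, n_out = 501)  # 500 h is an output point
  c_mid <- loss_over_window(full, 0, 500)  # percent lost by 500 h
  # restart from the stored state at 500 h with a phase-shifted forcing
  f2 <- sinusoid_forcing(f$mean, f$amplitude, f$period,
                         f$phase + 2 * pi * 500 / f$period)
  m2 <- dynamic_decay_model(c0 = 100 * (1 - c_mid / 100),
                            temperature_forcing = f2, rate_law = law)
  part <- simulate_decay(m2, 500)
  expect_equal(part$c[nrow(part)], full$c[nrow(full)], tolerance = 1e-6)
})

test_that("window losses compose multiplicatively", {
  law <- exp_rate_law(0.2834, 0.0435)
  m <- dynamic_decay_model(c0 = 100,
                           temperature_forcing = sinusoid_forcing(30, 0, 24),
                           rate_law = law)
  traj <- simulate_decay(m, 1460)  # two months
  p1 <- loss_over_window(traj, 0, 730) / 100
  p2 <- loss_over_window(traj, 730, 1460) / 100
  p12 <- loss_over_window(traj, 0, 1460) / 100
  expect_equal(1 - p12, (1 - p1) * (1 - p2), tolerance = 1e-9)
  expect_equal(loss_over_window(traj, 100, 100), 0)
  expect_equal(loss_over_window(traj, 0, 1460) , total_loss_percent(traj),
               tolerance = 1e-9)
  expect_error(loss_over_window(traj, 200, 100),
               class = "soildeg_invalid_input")
  expect_error(loss_over_window(traj, 0, 2000),
               class = "soildeg_invalid_input")
})

test_that("the hydrothermal product form drives seasonal slowdown", {
  tr <- temperature_response(q10 = 2, t_opt = 30)
  mr <- moisture_response(4.84, 2.35)
  m <- dynamic_decay_model(
    c0 = 100, temperature_forcing = moscow_like_forcing(),
    k_max = 1.5, moisture_response = mr, temperature_response = tr,
    moisture_forcing = sinusoid_forcing(mr$w_opt, 0, 8760))
  traj <- simulate_decay(m, 8760, n_out = 1200)
  # January (cold) loses less than July (warm)
  jan <- loss_over_window(traj, 0, 730)
  jul <- loss_over_window(traj, 4380, 5110)
  expect_lt(jan, jul)
  # with moisture pinned at the optimum, k(t) = k_max * m(T(t))
  expect_equal(traj$k_per_year[1],
               1.5 * temperature_factor(evaluate_forcing(
                 moscow_like_forcing(), 0), tr))
})

test_that("model construction enforces a single rate formulation", {
  law <- exp_rate_law(0.3, 0.04)
  f <- arid_forcing()
  expect_error(dynamic_decay_model(temperature_forcing = f),
               class = "soildeg_invalid_input")
  expect_error(dynamic_decay_model(temperature_forcing = f, rate_law = law,
                                   k_max = 1),
               class = "soildeg_invalid_input")
})

test_that("forcing files round trip through the readers", {
  path <- system.file("extdata", "temperate_annual_forcing_synthetic.csv",
                      package = "soildeg")
  f <- read_forcing_series(path)
  expect_s3_class(f$temperature, "tabulated_forcing")
  v <- evaluate_forcing(f$temperature, c(0, 4380))
  expect_equal(v[1], -7.54)
  expect_gt(v[2], 15)
  # trajectory writer round trip
  m <- dynamic_decay_model(c0 = 1, temperature_forcing = arid_forcing(),
                           rate_law = exp_rate_law(0.2834, 0.0435))
  traj <- simulate_decay(m, 100, n_out = 11)
  out <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, out)
  back <- load_dataset(out, c(time_h = "numeric", c = "numeric",
                              k_per_year = "numeric"))
  expect_equal(back$c, traj$c, tolerance = 1e-12)
})
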