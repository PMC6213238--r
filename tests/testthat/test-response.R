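test_that("temperature factor obeys the Q10 law", {
  tr <- temperature_response(q10 = 2, t_opt = 30)
  expect_equal(temperature_factor(30, tr), 1)
  expect_equal(temperature_factor(20, tr), 0.5)
  expect_equal(temperature_factor(25, tr), 2^-0.5)
  # exact decade ratio everywhere on the domain
  t <- seq(0, 20, by = 2.5)
  expect_equal(temperature_factor(t + 10, tr) / temperature_factor(t, tr),
               rep(2, length(t)))
  # above the optimum only with the explicit flag
  expect_error(temperature_factor(35, tr), class = "soildeg_invalid_input")
  expect_equal(temperature_factor(40, tr, extrapolate = TRUE), 2)
})

test_that("moisture factor is normalized, endpoint-zero and unimodal", {
  mr <- moisture_response(4.84, 2.35)
  expect_equal(mr$w_opt, 4.84 / (4.84 + 2.35))
  expect_equal(moisture_factor(mr$w_opt, mr), 1)
  expect_equal(moisture_factor(c(0, 1), mr), c(0, 0))
  expect_equal(moisture_factor(0.5, mr), 0.64, tolerance = 2e-2)
  expect_error(moisture_factor(1.2, mr), class = "soildeg_invalid_input")
  # strictly increasing below the optimum, strictly decreasing above
  w_lo <- seq(0.01, mr$w_opt, length.out = 200)
  w_hi <- seq(mr$w_opt, 0.99, length.out = 200)
  expect_true(all(diff(moisture_factor(w_lo, mr)) > 0))
  expect_true(all(diff(moisture_factor(w_hi, mr)) < 0))
})

test_that("extremum identity holds for the reported caption fits", {
  pairs <- list(c(4.84, 2.35, 0.67), c(4.27, 1.53, 0.74),
                c(2.54, 1.09, 0.70))
  for (p in pairs)
    expect_equal(round(moisture_response(p[1], p[2])$w_opt, 2), p[3])
})

test_that("combined rate peaks at the joint optimum", {
  tr <- temperature_response(q10 = 2, t_opt = 30)
  mr <- moisture_response(4.84, 2.35)
  expect_equal(combined_rate(30, mr$w_opt, tr, mr, u_max = 30), 30)
  expect_equal(combined_rate(20, mr$w_opt, tr, mr, u_max = 30), 15)
  # brute-force grid argmax lands on (t_opt, w_opt)
  grid <- expand.grid(t = seq(0, 30, by = 0.5), w = seq(0.01, 0.99, by = 0.01))
  u <- combined_rate(grid$t, grid$w, tr, mr, u_max = 30)
  best <- grid[which.max(u), ]
  expect_equal(best$t, 30)
  expect_equal(best$w, 0.67)  # grid point nearest w_opt = 0.673
  expect_lte(max(u), 30)
})

test_that("moisture-response fit recovers clean parameters exactly", {
  w <- seq(0.1, 0.95, by = 0.05)
  truth <- moisture_response(4.84, 2.35)
  u <- 30 * moisture_factor(w, truth)
  for (norm in c(TRUE, FALSE)) {
    fit <- fit_moisture_response(w, u, normalize = norm)
    expect_equal(fit$a, 4.84, tolerance = 1e-4)
    expect_equal(fit$b, 2.35, tolerance = 1e-4)
    expect_equal(fit$u_max, 30, tolerance = 1e-4)
    expect_equal(fit$w_opt, fit$a / (fit$a + fit$b))
  }
})

test_that("moisture-response fit rejects one-sided data", {
  mr <- moisture_response(4.84, 2.35)
  w <- seq(0.05, 0.5, by = 0.05)  # all below the optimum 0.673
  u <- 30 * moisture_factor(w, mr)
  expect_error(fit_moisture_response(w, u), class = "soildeg_fit_error")
  expect_error(fit_moisture_response(c(0.3, 0.5, 0.7), c(1, 2, 1)),
               class = "soildeg_invalid_input")  # too few points
})

test_that("noisy grids yield determination coefficients in the usual band", {
  # 30-point grids at 5% relative noise: R^2 overwhelmingly in 0.96-0.99,
  # approximation error s near 0.03-0.07
  w <- seq(0.08, 0.95, length.out = 30)
  truth <- moisture_response(4.84, 2.35)
  u0 <- 30 * moisture_factor(w, truth)
  stats <- t(vapply(1:200, function(seed) {
    u <- with_seed_test(seed, pmax(u0 + rnorm(30, sd = 0.05 * 30), 0))
    fit <- fit_moisture_response(w, u)
    c(r2 = attr(fit, "r_squared"), s = attr(fit, "approx_error"))
  }, c(r2 = 0, s = 0)))
  expect_gte(mean(stats[, "r2"] >= 0.96 & stats[, "r2"] <= 0.995), 0.9)
  expect_gte(mean(stats[, "s"] >= 0.02 & stats[, "s"] <= 0.08), 0.9)
})

test_that("fitted confidence intervals cover the generating parameters", {
  # 95% nominal coverage of (a, b) across seeds, +/- 2 SE on moderate noise
  w <- seq(0.08, 0.95, length.out = 30)
  truth <- moisture_response(4.84, 2.35)
  u0 <- 30 * moisture_factor(w, truth)
  cover <- vapply(1:100, function(seed) {
    u <- with_seed_test(seed, pmax(u0 + rnorm(30, sd = 0.03 * 30), 0))
    fit <- fit_moisture_response(w, u)
    se <- attr(fit, "std_errors")
    all(abs(c(fit$a - 4.84, fit$b - 2.35)) <= 2 * se[c("a", "b")])
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("exponential k(T) law reproduces its printed evaluations", {
  law <- exp_rate_law(0.2834, 0.0435)
  expect_equal(law$q10_implied, exp(0.435))
  # evaluations sit inside the incubation-derived constant ranges
  k37 <- rate_at_temperature(law, 37)
  expect_equal(k37, 1.42, tolerance = 5e-3)
  expect_true(k37 >= 0.7 && k37 <= 2.7)
  k20 <- rate_at_temperature(law, 20)
  expect_equal(k20, 0.68, tolerance = 1e-2)
  expect_true(k20 >= 0.2 && k20 <= 1.5)
})

test_that("k(T) fitting recovers the generating law", {
  law <- exp_rate_law(0.2834, 0.0435)
  t <- c(20, 30, 37)
  fit <- fit_rate_temperature(t, rate_at_temperature(law, t))
  expect_equal(fit$k0, 0.2834, tolerance = 1e-6)
  expect_equal(fit$s, 0.0435, tolerance = 1e-6)
  expect_error(fit_rate_temperature(c(20, 20, 30), c(1, 1, 2)),
               class = "soildeg_invalid_input")
})

test_that("joint surface fit works with fixed and free Q10", {
  tr <- temperature_response(q10 = 2, t_opt = 30)
  mr <- moisture_response(4.84, 2.35)
  g <- gen_response_grid(mr, tr, u_max = 30)
  fit <- fit_response_surface(g$temp_c, g$w_rel, g$u_m)
  expect_equal(fit$moisture_response$a, 4.84, tolerance = 1e-4)
  expect_equal(fit$u_max, 30, tolerance = 1e-4)
  fit2 <- fit_response_surface(g$temp_c, g$w_rel, g$u_m, q10 = NULL)
  expect_equal(fit2$temperature_response$q10, 2, tolerance = 1e-3)
})

test_that("fit reports serialize with the rendered formula", {
  w <- seq(0.1, 0.95, by = 0.05)
  u <- 30 * moisture_factor(w, moisture_response(4.84, 2.35))
  fit <- fit_moisture_response(w, u)
  f <- withr::local_tempfile(fileext = ".json")
  write_response_report(fit, f)
  rep <- jsonlite::read_json(f)
  expect_equal(rep$w_opt, fit$w_opt)
  expect_match(rep$formula, "^f\\(W\\) = \\(W/0\\.673")
})
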