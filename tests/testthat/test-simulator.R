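# The coupled heat/mass solver: limits, conservation, and result utilities.

test_that("a sealed surface conserves moisture while the fruit heats up", {
  spec <- blackberry_material("none")
  scen <- drying_scenario(air_state(338.15, 10), "none", 0, h = 10.61,
                          h_m = 1e-12, duration = 3600)
  sim <- simulate_drying(spec, scen, numerics_config(n_nodes = 41))
  expect_lt(max(abs(sim$W_avg - spec$W0)), 1e-6)
  # temperature approaches the air temperature from below
  expect_true(all(diff(sim$T_center) > -1e-9))
  expect_lt(abs(utils::tail(sim$T_center, 1) - 338.15),
            abs(spec$T0 - 338.15) / 4)
})

test_that("radial profiles keep a zero-gradient center and uniform start", {
  sim <- transient_simulation("airborne")
  expect_equal(sim$T[1, ], rep(sim$spec$T0, length(sim$xi)))
  expect_equal(sim$W[1, ], rep(sim$spec$W0, length(sim$xi)))
  # one-sided parabolic slope at the center stays negligible relative to
  # the surface-center span
  dxi <- sim$xi[2]
  n_t <- length(sim$times)
  for (k in c(round(n_t / 2), n_t)) {
    slope_c <- (-3 * sim$T[k, 1] + 4 * sim$T[k, 2] - sim$T[k, 3]) / (2 * dxi)
    span <- max(abs(sim$T[k, length(sim$xi)] - sim$T[k, 1]), 1e-6)
    expect_lt(abs(slope_c) / span, 0.05)
  }
})

test_that("acoustic surface flux raises the late-time surface temperature", {
  # identical transfer coefficients; the only difference is the 0.245 W
  # acoustic flux
  spec <- blackberry_material("airborne")
  base <- drying_scenario(air_state(338.15, 10), "none", 0, h = 24.54,
                          h_m = 0.02613, duration = 1800)
  sonic <- drying_scenario(air_state(338.15, 10), "airborne", 0.245,
                           h = 24.54, h_m = 0.02613, duration = 1800)
  n <- numerics_config(n_nodes = 41)
  s0 <- simulate_drying(spec, base, n)
  s1 <- simulate_drying(spec, sonic, n)
  late <- s0$times >= 900
  expect_true(all(s1$T_surface[late] > s0$T_surface[late]))
})

test_that("average_moisture integrates profiles by the trapezoid rule", {
  xi <- seq(0, 1, length.out = 121)
  expect_equal(average_moisture(rep(3.7, 121), xi), 3.7)
  # closed form: int(xi^4) / int(xi^2) = 3/5
  expect_equal(average_moisture(xi^2, xi), 0.6, tolerance = 1e-3)
  coarse <- seq(0, 1, length.out = 61)
  err_c <- abs(average_moisture(coarse^2, coarse) - 0.6)
  err_f <- abs(average_moisture(xi^2, xi) - 0.6)
  expect_lt(err_f, err_c)
  expect_error(average_moisture(1:3, c(0, 1)), "equal-length")
})

test_that("time_to_moisture interpolates between bracketing samples", {
  fake <- structure(list(times = c(0, 100, 200, 300),
                         W_avg = c(6, 4, 2, 1)),
                    class = "drying_simulation")
  expect_identical(time_to_moisture(fake, 6), 0)
  expect_equal(time_to_moisture(fake, 3), 150)     # midway between 4 and 2
  expect_equal(time_to_moisture(fake, 1.5), 250)
  expect_error(time_to_moisture(fake, 0.5), "not reached")
  expect_error(time_to_moisture(fake, 7), "not reached")
})

test_that("surface-center differences start at zero and peak early then decay", {
  sim <- transient_simulation("contact")
  d <- surface_center_difference(sim)
  expect_identical(d$dT[1], 0)
  expect_identical(d$dW[1], 0)
  ipk <- which.max(d$dT)
  expect_gt(d$dT[ipk], 0)
  expect_lt(d$time_s[ipk], 600)                    # early in a 30-min run
  expect_lt(d$dT[length(d$dT)], 0.6 * d$dT[ipk])   # decays after the peak
})

test_that("water lost by the fruit equals the evaporated mass at every output", {
  sim <- transient_simulation("none")
  expect_lt(mass_balance_residual(sim), 1e-3)
  # evaporated mass is non-decreasing while drying
  expect_true(all(diff(sim$evaporated) > -1e-12))
})

test_that("stop_at_moisture terminates the run at the requested average moisture", {
  sim <- mode_simulation("contact")
  expect_equal(utils::tail(sim$W_avg, 1), 1.0, tolerance = 1e-4)
  expect_lt(utils::tail(sim$times, 1), 24 * 3600)
})

test_that("scenario and numerics constructors enforce their invariants", {
  air <- air_state(338.15, 10)
  expect_error(drying_scenario(air, "none", 0.2, 10, 0.01, 100), "P_US")
  expect_error(drying_scenario(air, "contact", 0, 10, 0.01, 100), "P_US")
  expect_error(drying_scenario(air, "none", 0, -1, 0.01, 100), "positive")
  expect_error(numerics_config(n_nodes = 5), "at least 11")
  expect_error(numerics_config(rtol = -1), "positive")
})
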