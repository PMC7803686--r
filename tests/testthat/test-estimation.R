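# Parameter estimators: exact recovery on noiseless data generated from
# each estimator's own measurement model, plus the published
# transfer-coefficient arithmetic.

test_that("GAB fit recovers generating parameters exactly and is deterministic", {
  truth <- gab_params(W_m = 0.1, C = 10, K = 0.9)
  tab <- generate_sorption_points(truth)
  fit1 <- fit_gab(tab)
  fit2 <- fit_gab(tab)
  expect_equal(fit1$params$W_m, truth$W_m, tolerance = 1e-4)
  expect_equal(fit1$params$C, truth$C, tolerance = 1e-4)
  expect_equal(fit1$params$K, truth$K, tolerance = 1e-4)
  expect_identical(unclass(fit1$params), unclass(fit2$params))
  expect_gt(fit1$report$r_squared, 0.999999)
  expect_error(fit_gab(sorption_table(c(0.2, 0.4, 0.6, 0.8),
                                      c(0.1, 0.15, 0.25, 0.5))),
               "at least 5")
})

test_that("slope method inverts the one-term series and handles degenerate input", {
  p <- gab_params(0.1, 10, 0.9)
  W_eq <- gab_moisture(0.10, p)
  mat <- material_spec(3.5e-3, 0.138, r0 = 2.5e-3, gab = p,
                       arrhenius = arrhenius_params(1e-9, 0),
                       shrinkage = shrinkage_law(0.6068), T0 = 298.15)
  scen <- drying_scenario(air_state(338.15, 10), "none", 0, 10.61, 0.0113,
                          7200)
  ks <- generate_drying_kinetics(mat, scen, sampling = seq(0, 7200, 60))
  expect_equal(estimate_de_slope(ks, r = 2.5e-3, W_eq = W_eq), 1e-9,
               tolerance = 1e-3)

  # invariance under uniform re-sampling of the exact series
  ks2 <- generate_drying_kinetics(mat, scen, sampling = seq(0, 7200, 30))
  expect_equal(estimate_de_slope(ks2, r = 2.5e-3, W_eq = W_eq),
               estimate_de_slope(ks, r = 2.5e-3, W_eq = W_eq),
               tolerance = 1e-9)

  expect_error(estimate_de_slope(kinetics_series(0:10, rep(3, 11)), 2.5e-3),
               "constant-moisture")
})

test_that("slope method stays within 10% on the exact multi-term series", {
  De <- 1e-9; r <- 2.5e-3
  W0 <- 6.2464; W_eq <- 0.05
  t <- seq(0, 7200, 60)
  W <- W_eq + (W0 - W_eq) * mr_series_exact(t, De, r)
  W[1] <- W0
  De_hat <- estimate_de_slope(kinetics_series(t, W), r, W_eq = W_eq,
                              mr_threshold = 0.6)
  expect_equal(De_hat, De, tolerance = 0.1)
})

test_that("Arrhenius regression recovers the generating line", {
  # two exact points determine the line exactly
  p <- arrhenius_params(D0 = 5e-7, b = 2000)
  fit2 <- fit_arrhenius(c(320, 350), arrhenius_diffusivity(c(320, 350), p))
  expect_equal(fit2$D0, p$D0, tolerance = 1e-10)
  expect_equal(fit2$b, p$b, tolerance = 1e-10)

  # three points generated from the published hot-air fit (SI units)
  ph <- arrhenius_params(D0 = 2.608e-6 / 60, b = 1159)
  Tg <- c(323.15, 333.15, 343.15)
  fit3 <- fit_arrhenius(Tg, arrhenius_diffusivity(Tg, ph))
  expect_equal(fit3$b, 1159, tolerance = 1e-6)
  expect_equal(fit3$D0, ph$D0, tolerance = 1e-6)

  expect_error(fit_arrhenius(330, 1e-9), "length|distinct")
  expect_error(fit_arrhenius(c(330, 330), c(1e-9, 2e-9)), "distinct")
})

test_that("lumped-capacitance fit recovers h and matches the decay-rate identity", {
  cool <- generate_copper_cooling(24.54, T0 = 298.15, T_air = 338.15,
                                  sampling = seq(0, 1200, 10))
  fit <- fit_h_lumped(cool, T_air = 338.15)
  expect_equal(fit$h, 24.54, tolerance = 1e-3)
  expect_gt(fit$report$r_squared, 0.999999)

  # h = 26.61, d = 25 mm: rate constant h*3/(rho*Cp*radius) hand-evaluated
  sph <- copper_sphere()
  k_expected <- 26.61 * 3 / (8.96e3 * 390 * 0.0125)
  cool2 <- generate_copper_cooling(26.61, T0 = 298.15, T_air = 338.15,
                                   sampling = seq(0, 1200, 10))
  theta <- (cool2$T_surface - 338.15) / (298.15 - 338.15)
  k_fitted <- -stats::coef(stats::lm(log(theta) ~ cool2$time))[[2]]
  expect_equal(k_fitted, k_expected, tolerance = 1e-9)
  expect_equal(k_expected, 0.00182761, tolerance = 1e-5)

  short <- cooling_series(0:3, c(298, 305, 311, 316))
  expect_error(fit_h_lumped(short, T_air = 338.15), "at least 5")
  flat <- generate_copper_cooling(10, T0 = 338.0, T_air = 338.15,
                                  sampling = seq(0, 100, 10))
  expect_error(fit_h_lumped(flat, T_air = 338.15), "exceed 1 K")
})

test_that("Chilton-Colburn analogy reproduces the published coefficient pairs", {
  air <- air_state(338.15, 30)
  expect_equal(signif(hm_from_h(10.61, air), 4), 0.01130)
  expect_equal(signif(hm_from_h(24.54, air), 4), 0.02613)
  expect_equal(signif(hm_from_h(26.61, air), 4), 0.02833)
  expect_identical(hm_from_h(0, air), 0)
  expect_equal(hm_from_h(20, air), 2 * hm_from_h(10, air))
})

test_that("calorimetric power inverts the linear heating model", {
  cal <- generate_calorimetry(0.299, T0 = 298.15, sampling = seq(0, 120, 5))
  expect_equal(calorimetric_power(cal), 0.299, tolerance = 1e-3)

  cal2 <- generate_calorimetry(0.598, T0 = 298.15, sampling = seq(0, 120, 5))
  expect_equal(calorimetric_power(cal2), 2 * calorimetric_power(cal),
               tolerance = 1e-10)

  flat <- calorimetry_series(seq(0, 120, 5), rep(298.15, 25))
  expect_error(calorimetric_power(flat), "no heating")
})

test_that("acoustic intensity spreads power over the sphere surface", {
  expect_identical(ultrasound_intensity(0, 0.0125), 0)
  expect_equal(ultrasound_intensity(0.299, 0.0125), 152.3,
               tolerance = 0.2 / 152.3)
  expect_equal(ultrasound_intensity(0.299, 0.00625),
               4 * ultrasound_intensity(0.299, 0.0125))
  expect_error(ultrasound_intensity(0.1, 0), "positive")
})
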