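# Thermophysical correlations, sorption isotherm and geometry.

test_that("saturation vapor pressure matches steam-table anchors and is monotone", {
  # boiling point and 25 degC steam-table values
  expect_equal(saturation_vapor_pressure(373.15), 1.013e5, tolerance = 0.01)
  expect_equal(saturation_vapor_pressure(298.15), 3.17e3, tolerance = 0.02)
  expect_gt(saturation_vapor_pressure(338.15), saturation_vapor_pressure(323.15))
  expect_error(saturation_vapor_pressure(250), "273.15")
  expect_error(saturation_vapor_pressure(500), "473.15")
})

test_that("moist-food correlations evaluate correctly over their domains", {
  expect_identical(specific_heat(0), 837)
  expect_identical(specific_heat(1), 2093)
  expect_equal(specific_heat(6.2464), 8682.5, tolerance = 0.1 / 8682.5)
  expect_error(specific_heat(-0.1), "non-negative")

  expect_equal(latent_heat(273.15), 2501.05e3)
  expect_lt(latent_heat(647.3 - 1e-9), 1e-3 * latent_heat(273.15))
  expect_equal(latent_heat(338.15), 2348495.35, tolerance = 1e-6)
  expect_error(latent_heat(700), "critical")

  expect_equal(thermal_conductivity(0), 0.149)
  expect_equal(thermal_conductivity(1), 0.321)
  expect_equal(thermal_conductivity(1e6), 0.493, tolerance = 1e-3)
  expect_error(thermal_conductivity(-1), "non-negative")
})

test_that("GAB isotherm evaluates, inverts analytically, and matches a bisection oracle", {
  p <- gab_params(W_m = 0.1, C = 10, K = 0.8)
  expect_identical(gab_moisture(0, p), 0)
  # direct substitution, cross-checked against a root-found inverse
  expect_equal(gab_moisture(0.5, p), 0.14492753623, tolerance = 1e-10)

  p2 <- gab_params(0.1, 10, 0.9)
  expect_equal(gab_water_activity(0.3, p2), 0.75727383749, tolerance = 1e-8)
  expect_identical(gab_water_activity(0, p2), 0)

  # round-trip and bisection-oracle agreement over random valid parameters
  set.seed(11)
  for (i in 1:25) {
    pr <- gab_params(W_m = runif(1, 0.05, 0.3), C = runif(1, 1, 50),
                     K = runif(1, 0.3, 0.95))
    aw <- runif(4, 0.02, 0.95)
    W <- gab_moisture(aw, pr)
    expect_equal(gab_water_activity(W, pr), aw, tolerance = 1e-8)
    # independent bisection on the forward isotherm
    for (j in seq_along(W)) {
      aw_bis <- stats::uniroot(function(a) gab_moisture(a, pr) - W[j],
                               c(0, 0.99999 / pr$K), tol = 1e-12)$root
      expect_equal(gab_water_activity(W[j], pr), aw_bis, tolerance = 1e-8)
    }
  }
  expect_error(gab_moisture(1.5, p2), "a_w")
  expect_warning(gab_water_activity(50, p2), "clamped")
})

test_that("density definitions are mutually consistent and scale cubically", {
  expect_equal(solid_density(0.0035, 0.138, 0.0125), 59.0, tolerance = 0.1 / 59)
  expect_equal(bulk_density(6.2464, 0.0035, 0.138, 0.0125), 427.8099,
               tolerance = 1e-6)
  expect_equal(solid_density(1, 0.5, 0.005) / solid_density(1, 0.5, 0.01), 8)
  set.seed(7)
  for (i in 1:20) {
    W <- runif(1, 0, 7); M0 <- runif(1, 1e-3, 1e-2); r <- runif(1, 1e-3, 2e-2)
    expect_equal(bulk_density(W, M0, 0.138, r),
                 (1 + W) * solid_density(M0, 0.138, r))
  }
  expect_equal(bulk_density(0, 0.0035, 0.138, 0.0125),
               solid_density(0.0035, 0.138, 0.0125))
  expect_error(solid_density(0.0035, 0.138, 0), "positive")
})

test_that("vapor concentrations are linear in their driving variables", {
  expect_identical(vapor_concentration_surface(338.15, 0), 0)
  expect_equal(vapor_concentration_surface(338.15, 0.5),
               0.5 * vapor_concentration_surface(338.15, 1))
  expect_equal(vapor_concentration_surface(338.15, 1), 0.15949780,
               tolerance = 1e-7)
  expect_identical(vapor_concentration_air(air_state(338.15, 0)), 0)
  expect_equal(vapor_concentration_air(air_state(338.15, 30)), 0.04784934,
               tolerance = 1e-7)
  expect_equal(vapor_concentration_air(air_state(338.15, 100)),
               vapor_concentration_surface(338.15, 1))
  expect_error(vapor_concentration_surface(338.15, 1.2), "\\[0, 1\\]")
})

test_that("shrinkage law maps moisture to radius and rejects bad inputs", {
  spec <- blackberry_material("none")
  expect_equal(radius_from_moisture(spec$W0, spec), spec$r0)
  # hot-air-alone slope 0.6068: fully dry radius ratio 0.3932
  expect_equal(radius_from_moisture(0, spec), 0.3932 * spec$r0)
  W <- seq(0, spec$W0, length.out = 30)
  expect_true(all(diff(radius_from_moisture(W, spec)) > 0))
  expect_error(radius_from_moisture(spec$W0 + 1, spec), "W0")
  expect_error(shrinkage_law(0.5, intercept = 0.4), "equal 1")
  expect_error(shrinkage_law(1.2), "non-positive radius")
})

test_that("Arrhenius diffusivity behaves and matches the published hot-air fit", {
  p0 <- arrhenius_params(D0 = 3e-9, b = 0)
  expect_equal(arrhenius_diffusivity(c(300, 350, 400), p0), rep(3e-9, 3))
  p <- arrhenius_params(D0 = 2.608e-6 / 60, b = 1159)
  Tg <- seq(300, 360, 10)
  expect_true(all(diff(arrhenius_diffusivity(Tg, p)) > 0))
  expect_equal(arrhenius_diffusivity(338.15, p), 1.4113142e-9,
               tolerance = 1e-7)
  expect_equal(p$Ea, 1159 * 8.314e-3)
})

test_that("initial moisture follows from the dry-mass fraction", {
  expect_equal(round(initial_moisture_from_dry_fraction(0.138), 2), 6.25)
  expect_identical(initial_moisture_from_dry_fraction(0.5), 1)
  expect_equal(initial_moisture_from_dry_fraction(0.999), 0.001001001,
               tolerance = 1e-6)
  expect_error(initial_moisture_from_dry_fraction(0), "\\(0, 1\\)")
  expect_error(initial_moisture_from_dry_fraction(1), "\\(0, 1\\)")
})

test_that("parameter constructors validate their invariants", {
  expect_error(gab_params(-0.1, 10, 0.9), "W_m")
  expect_error(gab_params(0.1, 10, 1.2), "\\(0, 1\\)")
  expect_error(arrhenius_params(-1, 100), "D0")
  expect_error(air_state(338.15, 120), "RH")
  expect_error(air_state(-2, 50), "positive")
  expect_error(material_spec(0, 0.138, 0.0125, blackberry_gab_default(),
                             arrhenius_params(1e-9, 0), shrinkage_law(0.5)),
               "M0")
  spec <- blackberry_material("contact")
  expect_equal(spec$W0, (1 - 0.138) / 0.138)
})
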