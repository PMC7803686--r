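# Seeded synthetic generators for the four experimental inputs: drying
# kinetics, copper-sphere cooling, calorimetry, and sorption equilibrium.
# Each generator evaluates the corresponding measurement model exactly and
# then applies the requested noise, so every estimator has a closed loop
# back to its generating truth.

#' Measurement-noise specification
#'
#' @param kind `"gaussian_additive"` (sigma in the units of the target
#'   variable) or `"gaussian_multiplicative"` (sigma relative).
#' @param sigma Noise scale, >= 0.
#' @param seed Integer seed; identical seeds give identical series.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("gaussian_additive", "gaussian_multiplicative"),
                       sigma = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

.apply_noise <- function(x, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$sigma == 0) return(x)
  set.seed(noise$seed)
  eps <- stats::rnorm(length(x), mean = 0, sd = noise$sigma)
  switch(noise$kind,
         gaussian_additive = x + eps,
         gaussian_multiplicative = x * (1 + eps))
}

#' Default water-activity grid of the sorption experiment
#'
#' Nominal water activities of the seven saturated salt solutions (LiCl,
#' CH3COOK, MgCl2, K2CO3, KI, NaCl, KCl) near 65 degC.  The values are
#' nominal, synthetic defaults.
#'
#' @return A numeric vector of 7 water activities.
#' @export
default_aw_grid <- function() c(0.11, 0.22, 0.33, 0.43, 0.69, 0.75, 0.84)

#' Generate a synthetic drying-kinetics series
#'
#' Either from the one-term sphere-diffusion solution (the slope-method
#' measurement model) or from the full coupled simulation.  The initial
#' sample is the exact initial moisture; noise is applied afterwards and
#' the series floored at the equilibrium moisture.
#'
#' @param spec A [material_spec()].
#' @param scenario A [drying_scenario()].
#' @param sampling Sample times (s), strictly increasing from 0.
#' @param noise A [noise_spec()]; default noiseless.
#' @param generator `"one_term"` (constant `De` at the air temperature,
#'   fixed radius `r0`) or `"full_model"`.
#' @param W_eq Equilibrium moisture; defaults to the isotherm value at the
#'   air water activity `RH/100`.
#' @param numerics Passed to [simulate_drying()] for `"full_model"`.
#' @return A [kinetics_series()].
#' @export
generate_drying_kinetics <- function(spec, scenario, sampling,
                                     noise = noise_spec(),
                                     generator = c("one_term", "full_model"),
                                     W_eq = NULL,
                                     numerics = numerics_config()) {
  generator <- match.arg(generator)
  stopifnot(inherits(spec, "material_spec"),
            inherits(scenario, "drying_scenario"))
  .check_series_time(sampling)
  if (sampling[1L] != 0)
    stop("`sampling` must start at 0", call. = FALSE)
  if (is.null(W_eq))
    W_eq <- gab_moisture(min(scenario$air$RH / 100, 0.9999 / spec$gab$K),
                         spec$gab)
  W0 <- spec$W0
  if (generator == "one_term") {
    De <- arrhenius_diffusivity(scenario$air$T_air, spec$arrhenius)
    mr <- 6 / pi^2 * exp(-De * pi^2 * sampling / spec$r0^2)
    W <- W_eq + (W0 - W_eq) * mr
    W[1L] <- W0                      # physical initial condition
  } else {
    sim <- simulate_drying(spec, scenario, numerics,
                           times = unique(c(sampling, scenario$duration)))
    W <- stats::approx(sim$times, sim$W_avg, xout = sampling, rule = 2)$y
  }
  W <- pmax(.apply_noise(W, noise), W_eq)
  kinetics_series(time = sampling, moisture = W,
                  temperature = scenario$air$T_air, mode = scenario$mode)
}

#' Generate a synthetic copper-sphere cooling series
#'
#' Exponential lumped-capacitance response
#' `T(t) = T_air + (T0 - T_air) exp(-h A t / (rho Cp V))` plus noise.
#'
#' @param h_true True heat transfer coefficient (W m^-2 K^-1).
#' @param sphere A [copper_sphere()].
#' @param T0 Initial sphere temperature (K).
#' @param T_air Air temperature (K).
#' @param sampling Sample times (s), strictly increasing.
#' @param noise A [noise_spec()]; default noiseless.
#' @return A [cooling_series()].
#' @export
generate_copper_cooling <- function(h_true, sphere = copper_sphere(),
                                    T0, T_air, sampling,
                                    noise = noise_spec()) {
  if (h_true <= 0) stop("`h_true` must be positive", call. = FALSE)
  if (T0 == T_air) stop("`T0` must differ from `T_air`", call. = FALSE)
  .check_series_time(sampling)
  k <- h_true * 3 / (sphere$rho * sphere$Cp * sphere$radius)
  Ts <- T_air + (T0 - T_air) * exp(-k * sampling)
  cooling_series(time = sampling, T_surface = .apply_noise(Ts, noise),
                 sphere = sphere)
}

#' Generate a synthetic calorimetry series
#'
#' Linear temperature rise `T(t) = T0 + P t / (m Cp)` of an insulated
#' absorber sphere plus noise.
#'
#' @param P_true True dissipated power (W, >= 0).
#' @param sphere A [copper_sphere()].
#' @param T0 Initial temperature (K).
#' @param sampling Sample times (s), strictly increasing.
#' @param noise A [noise_spec()]; default noiseless.
#' @return A [calorimetry_series()].
#' @export
generate_calorimetry <- function(P_true, sphere = copper_sphere(), T0 = 298.15,
                                 sampling, noise = noise_spec()) {
  if (P_true < 0) stop("`P_true` must be non-negative", call. = FALSE)
  .check_series_time(sampling)
  temp <- T0 + P_true / (sphere$mass * sphere$Cp) * sampling
  calorimetry_series(time = sampling, temperature = .apply_noise(temp, noise))
}

#' Generate a synthetic sorption-equilibrium table
#'
#' Evaluates a GAB isotherm on a water-activity grid and perturbs the
#' equilibrium moistures.
#'
#' @param params A [gab_params()] truth.
#' @param a_w_grid Water activities, default [default_aw_grid()].
#' @param noise A [noise_spec()]; default noiseless.
#' @return A [sorption_table()].
#' @export
generate_sorption_points <- function(params, a_w_grid = default_aw_grid(),
                                     noise = noise_spec()) {
  if (any(a_w_grid <= 0) || any(a_w_grid >= 1))
    stop("`a_w_grid` must lie strictly inside (0, 1)", call. = FALSE)
  W <- gab_moisture(a_w_grid, params)
  sorption_table(a_w = a_w_grid,
                 W_eq = pmax(.apply_noise(W, noise), 1e-6))
}
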