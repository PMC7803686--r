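# Thermophysical correlations, sorption isotherm and geometry for a drying
# spherical fruit.  Everything here is pure and stateless; all units are SI
# (K, s, m, kg) with dry-basis moisture W in kg water / kg dry matter.

#' GAB sorption isotherm parameters
#'
#' Three-parameter Guggenheim-Anderson-De Boer isotherm linking water
#' activity to equilibrium dry-basis moisture,
#' \deqn{W_{eq} = \frac{W_m C K a_w}{(1 - K a_w)(1 - K a_w + C K a_w)}.}
#'
#' @param W_m Monolayer moisture content (kg water / kg dry matter).
#' @param C Energy constant (dimensionless, > 0).
#' @param K Correction constant (dimensionless, in (0, 1) so the isotherm
#'   stays finite on the whole water-activity range).
#' @return An object of class `gab_params`.
#' @examples
#' p <- gab_params(W_m = 0.10, C = 10, K = 0.90)
#' gab_moisture(0.5, p)
#' @export
gab_params <- function(W_m, C, K) {
  if (!is.numeric(W_m) || length(W_m) != 1L || W_m <= 0)
    stop("`W_m` must be a single positive number", call. = FALSE)
  if (!is.numeric(C) || length(C) != 1L || C <= 0)
    stop("`C` must be a single positive number", call. = FALSE)
  if (!is.numeric(K) || length(K) != 1L || K <= 0 || K >= 1)
    stop("`K` must be a single number in (0, 1)", call. = FALSE)
  structure(list(W_m = W_m, C = C, K = K), class = "gab_params")
}

#' Arrhenius parameters for the effective moisture diffusivity
#'
#' Temperature dependence \eqn{D_e(T) = D_0 \exp(-b/T)} with
#' \eqn{b = E_a / R_g}.
#'
#' @param D0 Pre-exponential factor (m^2 s^-1, > 0).
#' @param b Activation temperature `Ea / Rg` (K, >= 0).
#' @return An object of class `arrhenius_params` carrying `D0`, `b` and the
#'   implied activation energy `Ea` in kJ mol^-1 (gas constant
#'   8.314e-3 kJ mol^-1 K^-1).
#' @export
arrhenius_params <- function(D0, b) {
  if (!is.numeric(D0) || length(D0) != 1L || D0 <= 0)
    stop("`D0` must be a single positive number", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L)
    stop("`b` must be a single number", call. = FALSE)
  structure(list(D0 = D0, b = b, Ea = b * 8.314e-3),
            class = "arrhenius_params")
}

#' Linear shrinkage law
#'
#' Empirical linear relation between the radius ratio and the dry-basis
#' moisture ratio, `r/r0 = intercept + slope * W/W0`.  Fresh fruit
#' (`W = W0`) must map to the fresh radius, so `intercept = 1 - slope`.
#'
#' @param slope Dimensionless slope of radius ratio against moisture ratio.
#' @param intercept Dimensionless intercept; defaults to `1 - slope`.
#' @return An object of class `shrinkage_law`.
#' @export
shrinkage_law <- function(slope, intercept = 1 - slope) {
  if (!is.numeric(slope) || length(slope) != 1L)
    stop("`slope` must be a single number", call. = FALSE)
  if (abs(intercept + slope - 1) > 1e-9)
    stop("`intercept + slope` must equal 1 (fresh fruit keeps its radius)",
         call. = FALSE)
  if (intercept <= 0)
    stop("shrinkage law gives non-positive radius at zero moisture",
         call. = FALSE)
  structure(list(slope = slope, intercept = intercept),
            class = "shrinkage_law")
}

#' Intrinsic material description of the drying fruit
#'
#' Bundles every material-side parameter of the model: initial mass and
#' radius, dry-mass fraction, sorption isotherm, Arrhenius diffusivity and
#' shrinkage law.
#'
#' @param M0 Initial fruit mass (kg).
#' @param f_dm Dry-mass fraction of the fresh fruit (dimensionless in
#'   (0, 1); 0.138 for fresh blackberry).
#' @param r0 Initial radius (m).
#' @param gab A [gab_params()] object.
#' @param arrhenius An [arrhenius_params()] object.
#' @param shrinkage A [shrinkage_law()] object.
#' @param T0 Initial (uniform) temperature (K).
#' @return An object of class `material_spec`; its `W0` element is the
#'   initial dry-basis moisture `(1 - f_dm)/f_dm`.
#' @export
material_spec <- function(M0, f_dm, r0, gab, arrhenius, shrinkage,
                          T0 = 298.15) {
  if (!is.numeric(M0) || length(M0) != 1L || M0 <= 0)
    stop("`M0` must be a single positive number", call. = FALSE)
  if (!is.numeric(f_dm) || length(f_dm) != 1L || f_dm <= 0 || f_dm >= 1)
    stop("`f_dm` must be a single number in (0, 1)", call. = FALSE)
  if (!is.numeric(r0) || length(r0) != 1L || r0 <= 0)
    stop("`r0` must be a single positive number", call. = FALSE)
  if (!inherits(gab, "gab_params"))
    stop("`gab` must be a gab_params object", call. = FALSE)
  if (!inherits(arrhenius, "arrhenius_params"))
    stop("`arrhenius` must be an arrhenius_params object", call. = FALSE)
  if (!inherits(shrinkage, "shrinkage_law"))
    stop("`shrinkage` must be a shrinkage_law object", call. = FALSE)
  if (!is.numeric(T0) || length(T0) != 1L || T0 <= 0)
    stop("`T0` must be a single positive temperature in K", call. = FALSE)
  structure(list(M0 = M0, f_dm = f_dm, r0 = r0, gab = gab,
                 arrhenius = arrhenius, shrinkage = shrinkage, T0 = T0,
                 W0 = (1 - f_dm) / f_dm),
            class = "material_spec")
}

#' Drying-air state
#'
#' Temperature, humidity and the transport properties of the drying air
#' used by the vapor-concentration and Chilton-Colburn relations.
#'
#' @param T_air Air temperature (K).
#' @param RH Relative humidity in percent (0-100).
#' @param rho_air Air density (kg m^-3).
#' @param Cp_air Air specific heat (J kg^-1 K^-1).
#' @param alpha_air Air thermal diffusivity (m^2 s^-1).
#' @param D_air Diffusivity of water vapor in air (m^2 s^-1).
#' @return An object of class `air_state`.
#' @export
air_state <- function(T_air, RH, rho_air = 1.029, Cp_air = 1.0e3,
                      alpha_air = 2.5e-5, D_air = 2.18e-5) {
  vals <- c(T_air = T_air, rho_air = rho_air, Cp_air = Cp_air,
            alpha_air = alpha_air, D_air = D_air)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("air properties must all be strictly positive", call. = FALSE)
  if (!is.numeric(RH) || length(RH) != 1L || RH < 0 || RH > 100)
    stop("`RH` must be in [0, 100] percent", call. = FALSE)
  structure(list(T_air = T_air, RH = RH, rho_air = rho_air,
                 Cp_air = Cp_air, alpha_air = alpha_air, D_air = D_air),
            class = "air_state")
}

# unchecked scalar/vector core, shared with the ODE right-hand side where
# range checking would be wasted work
.psat <- function(T) {
  exp(-5.8e3 / T + 1.391 - 4.864e-2 * T + 4.176e-5 * T^2 -
        1.445e-8 * T^3 + 6.545 * log(T))
}

#' Saturation pressure of water vapor
#'
#' Empirical correlation for the saturation pressure over liquid water,
#' valid between 273.15 K and 473.15 K.
#'
#' @param T Temperature (K).
#' @return Saturation pressure (Pa).
#' @export
saturation_vapor_pressure <- function(T) {
  if (any(!is.finite(T)) || any(T < 273.15) || any(T > 473.15))
    stop("`T` must lie in [273.15, 473.15] K", call. = FALSE)
  .psat(T)
}

#' Specific heat of the wet fruit
#'
#' `Cp = (0.837 + 1.256 W) * 1000`, a linear mixing rule in dry-basis
#' moisture.
#'
#' @param W Dry-basis moisture (kg water / kg dry matter, >= 0).
#' @return Specific heat (J kg^-1 K^-1).
#' @export
specific_heat <- function(W) {
  if (any(!is.finite(W)) || any(W < 0))
    stop("`W` must be non-negative", call. = FALSE)
  (0.837 + 1.256 * W) * 1000
}

#' Latent heat of water evaporation
#'
#' `h_fg = 2501.05e3 * ((647.3 - T)/(647.3 - 273.15))^0.3298`, a Watson-type
#' correlation anchored at 273.15 K and vanishing at the critical point.
#'
#' @param T Temperature (K), strictly below the critical 647.3 K.
#' @return Latent heat (J kg^-1).
#' @export
latent_heat <- function(T) {
  if (any(!is.finite(T)) || any(T >= 647.3))
    stop("`T` must be below the critical temperature 647.3 K", call. = FALSE)
  2501.05e3 * ((647.3 - T) / (647.3 - 273.15))^0.3298
}

#' Thermal conductivity of the wet fruit
#'
#' `lambda = (0.149 + 0.493 W)/(1 + W)`, interpolating between dry solids
#' (0.149) and a water-dominated limit (0.493 W m^-1 K^-1).
#'
#' @param W Dry-basis moisture (kg water / kg dry matter, >= 0).
#' @return Thermal conductivity (W m^-1 K^-1).
#' @export
thermal_conductivity <- function(W) {
  if (any(!is.finite(W)) || any(W < 0))
    stop("`W` must be non-negative", call. = FALSE)
  (0.149 + 0.493 * W) / (1 + W)
}

#' Equilibrium moisture from water activity (GAB isotherm)
#'
#' @param a_w Water activity, in `[0, 1/K)`.
#' @param params A [gab_params()] object.
#' @return Equilibrium dry-basis moisture (kg water / kg dry matter).
#' @seealso [gab_water_activity()] for the analytic inverse.
#' @export
gab_moisture <- function(a_w, params) {
  stopifnot(inherits(params, "gab_params"))
  if (any(!is.finite(a_w)) || any(a_w < 0) || any(a_w >= 1 / params$K))
    stop(sprintf("`a_w` must lie in [0, %.4f) for these GAB parameters",
                 1 / params$K), call. = FALSE)
  u <- params$K * a_w
  params$W_m * params$C * u / ((1 - u) * (1 - u + params$C * u))
}

# inverse isotherm without clamping warnings, vector-safe in W
.gab_aw <- function(W, params) {
  W_m <- params$W_m; C <- params$C; K <- params$K
  # The isotherm is quadratic in u = K * a_w:
  #   W (1 - C) u^2 + (W (C - 2) - W_m C) u + W = 0
  A <- W * (1 - C)
  B <- W * (C - 2) - W_m * C
  aw <- numeric(length(W))
  for (i in seq_along(W)) {
    if (W[i] <= 0) { aw[i] <- 0; next }
    if (abs(A[i]) < 1e-300) {           # C == 1 collapses to a linear form
      u <- -W[i] / B[i]
    } else {
      disc <- B[i]^2 - 4 * A[i] * W[i]
      if (disc < 0) { aw[i] <- NA_real_; next }
      r1 <- (-B[i] + sqrt(disc)) / (2 * A[i])
      r2 <- (-B[i] - sqrt(disc)) / (2 * A[i])
      cand <- c(r1, r2)
      cand <- cand[cand > 0 & cand < 1]  # u = K a_w must lie in (0, K) <= (0,1)
      u <- if (length(cand)) min(cand) else NA_real_
    }
    aw[i] <- u / K
  }
  aw
}

#' Water activity from moisture (inverse GAB isotherm)
#'
#' Analytic inversion of the GAB isotherm, which is quadratic in
#' `K * a_w`; the root on `[0, 1)` is returned.  Results are clamped to
#' `[0, 0.9999]` so that downstream vapor-pressure arithmetic never crosses
#' the isotherm pole; moistures above the isotherm range clamp to the
#' ceiling with a warning.
#'
#' @param W Dry-basis moisture (kg water / kg dry matter, >= 0).
#' @param params A [gab_params()] object.
#' @return Water activity in `[0, 0.9999]`.
#' @export
gab_water_activity <- function(W, params) {
  stopifnot(inherits(params, "gab_params"))
  if (any(!is.finite(W)) || any(W < 0))
    stop("`W` must be non-negative", call. = FALSE)
  aw <- .gab_aw(W, params)
  bad <- is.na(aw) | aw > 0.9999
  if (any(bad))
    warning("water activity clamped to 0.9999 for moisture beyond the ",
            "isotherm range", call. = FALSE)
  aw[bad] <- 0.9999
  pmin(pmax(aw, 0), 0.9999)
}

#' Water-vapor concentration at the fruit surface
#'
#' Ideal-gas vapor concentration `2.1667e-3 * a_w * p_vs(T_s) / T_s`.
#'
#' @param T_s Surface temperature (K).
#' @param a_w Surface water activity in `[0, 1]`.
#' @return Vapor concentration (kg m^-3).
#' @export
vapor_concentration_surface <- function(T_s, a_w) {
  if (any(a_w < 0) || any(a_w > 1))
    stop("`a_w` must lie in [0, 1]", call. = FALSE)
  2.1667e-3 * a_w * saturation_vapor_pressure(T_s) / T_s
}

#' Water-vapor concentration of the drying air
#'
#' Ideal-gas vapor concentration `2.1667e-3 * (RH/100) * p_vs(T_air)/T_air`.
#'
#' @param air An [air_state()] object.
#' @return Vapor concentration (kg m^-3).
#' @export
vapor_concentration_air <- function(air) {
  stopifnot(inherits(air, "air_state"))
  2.1667e-3 * (air$RH / 100) * saturation_vapor_pressure(air$T_air) / air$T_air
}

#' Solid (dry-matter) density of the shrinking fruit
#'
#' Dry mass `M0 * f_dm` over the current spherical volume.
#'
#' @param M0 Initial fruit mass (kg).
#' @param f_dm Dry-mass fraction (dimensionless).
#' @param r Current radius (m, > 0).
#' @return Solid density (kg m^-3).
#' @export
solid_density <- function(M0, f_dm, r) {
  if (any(r <= 0)) stop("`r` must be positive", call. = FALSE)
  M0 * f_dm / (4 / 3 * pi * r^3)
}

#' Bulk density of the shrinking fruit
#'
#' Total (wet) mass over the current spherical volume; algebraically
#' `(1 + W) * solid_density`.
#'
#' @param W Dry-basis moisture (kg water / kg dry matter, >= 0).
#' @inheritParams solid_density
#' @return Bulk density (kg m^-3).
#' @export
bulk_density <- function(W, M0, f_dm, r) {
  if (any(W < 0)) stop("`W` must be non-negative", call. = FALSE)
  (W + 1) * solid_density(M0, f_dm, r)
}

#' Radius of the shrinking fruit at a given average moisture
#'
#' Applies the material's linear shrinkage law to the volume-average
#' dry-basis moisture.
#'
#' @param W_avg Volume-average dry-basis moisture, in `[0, W0]`.
#' @param spec A [material_spec()] object.
#' @return Radius (m).
#' @export
radius_from_moisture <- function(W_avg, spec) {
  stopifnot(inherits(spec, "material_spec"))
  if (any(W_avg < 0) || any(W_avg > spec$W0 * (1 + 1e-9)))
    stop("`W_avg` must lie in [0, W0]", call. = FALSE)
  spec$r0 * (spec$shrinkage$intercept +
               spec$shrinkage$slope * W_avg / spec$W0)
}

#' Effective moisture diffusivity at a given temperature
#'
#' Arrhenius law `De(T) = D0 * exp(-b / T)`.
#'
#' @param T Temperature (K, > 0).
#' @param params An [arrhenius_params()] object.
#' @return Effective diffusivity (m^2 s^-1).
#' @export
arrhenius_diffusivity <- function(T, params) {
  stopifnot(inherits(params, "arrhenius_params"))
  if (any(T <= 0)) stop("`T` must be positive (K)", call. = FALSE)
  params$D0 * exp(-params$b / T)
}

#' Initial dry-basis moisture from the dry-mass fraction
#'
#' `W0 = (1 - f_dm) / f_dm`; e.g. a dry-mass fraction of 0.138 gives an
#' initial moisture of 6.25 kg water / kg dry matter.
#'
#' @param f_dm Dry-mass fraction, in (0, 1).
#' @return Initial dry-basis moisture (kg water / kg dry matter).
#' @export
initial_moisture_from_dry_fraction <- function(f_dm) {
  if (any(!is.finite(f_dm)) || any(f_dm <= 0) || any(f_dm >= 1))
    stop("`f_dm` must lie in (0, 1)", call. = FALSE)
  (1 - f_dm) / f_dm
}
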