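# Reference calibration for blackberry drying at 65 degC, assembled from the
# published Arrhenius diffusivity fits, shrinkage slopes, transfer
# coefficients and calorimetric ultrasound powers for the three treatment
# modes.  The GAB parameters, initial radius/temperature and air humidity
# are NOT published for this calibration; the defaults used here are
# synthetic, realistic values documented in the methods vignette.

.mode_match <- function(mode) match.arg(mode, c("none", "airborne", "contact"))

# published Arrhenius fits are printed in m^2 min^-1; stored here in SI
.blackberry_arrhenius <- list(
  none     = c(D0 = 2.608e-6 / 60,  b = 1159),
  airborne = c(D0 = 0.007628 / 60,  b = 3562),
  contact  = c(D0 = 2.98e-5 / 60,   b = 1650)
)

.blackberry_shrinkage_slope <- c(none = 0.6068, airborne = 0.4365,
                                 contact = 0.3656)

.blackberry_h  <- c(none = 10.61, airborne = 24.54, contact = 26.61)
.blackberry_hm <- c(none = 0.01130, airborne = 0.02613, contact = 0.02833)
.blackberry_P  <- c(none = 0, airborne = 0.245, contact = 0.299)

#' Default (synthetic) GAB parameters for blackberry at 65 degC
#'
#' The published calibration never prints its fitted GAB constants, so this
#' default is a synthetic stand-in chosen to be realistic for a
#' sugar-rich berry: monolayer moisture 0.10 kg/kg DM, C = 10, K = 0.90.
#'
#' @return A [gab_params()] object.
#' @export
blackberry_gab_default <- function() gab_params(W_m = 0.10, C = 10, K = 0.90)

#' Reference material description of a blackberry fruit
#'
#' Assembles a [material_spec()] for one drying mode: dry-mass fraction
#' 0.138, the mode's published Arrhenius diffusivity fit (converted from
#' per-minute to SI) and shrinkage slope, and configurable mass, radius,
#' initial temperature and isotherm.
#'
#' @param mode Treatment: `"none"` (hot air alone), `"airborne"` or
#'   `"contact"` sonication.
#' @param M0 Initial mass (kg); default 3.5 g.
#' @param r0 Initial radius (m); default 0.0125 m, the radius of the copper
#'   analogue sphere used for the transfer-coefficient measurements.
#' @param T0 Initial temperature (K); default 298.15 K (room temperature).
#' @param gab GAB isotherm parameters; default [blackberry_gab_default()].
#' @param f_dm Dry-mass fraction; default 0.138.
#' @return A [material_spec()] object.
#' @export
blackberry_material <- function(mode = c("none", "airborne", "contact"),
                                M0 = 3.5e-3, r0 = 0.0125, T0 = 298.15,
                                gab = blackberry_gab_default(),
                                f_dm = 0.138) {
  mode <- .mode_match(mode)
  arr <- .blackberry_arrhenius[[mode]]
  material_spec(M0 = M0, f_dm = f_dm, r0 = r0, gab = gab,
                arrhenius = arrhenius_params(D0 = arr[["D0"]], b = arr[["b"]]),
                shrinkage = shrinkage_law(.blackberry_shrinkage_slope[[mode]]),
                T0 = T0)
}

#' Reference drying scenario for blackberry at 65 degC
#'
#' Air at 65 degC with the published heat/mass transfer coefficients and
#' calorimetric ultrasound power for the requested mode (h = 10.61 / 24.54 /
#' 26.61 W m^-2 K^-1, h_m = 0.01130 / 0.02613 / 0.02833 m s^-1,
#' P_US = 0 / 0.245 / 0.299 W for none / airborne / contact).
#'
#' @inheritParams blackberry_material
#' @param RH Air relative humidity in percent; the published runs do not
#'   state it, default 10 (ambient air heated to 65 degC).
#' @param duration Simulated duration (s).
#' @return A [drying_scenario()] object.
#' @export
blackberry_scenario <- function(mode = c("none", "airborne", "contact"),
                                RH = 10, duration = 6 * 3600) {
  mode <- .mode_match(mode)
  drying_scenario(air = air_state(T_air = 338.15, RH = RH),
                  mode = mode,
                  P_US = .blackberry_P[[mode]],
                  h = .blackberry_h[[mode]],
                  h_m = .blackberry_hm[[mode]],
                  duration = duration)
}
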