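# Hierarchical YAML configuration: material, air, scenario, numerics and
# noise sections with all defaults embedded, plus builders turning a config
# into the package's parameter objects.

#' Default configuration
#'
#' The full default configuration of the pipeline as a nested list:
#' `material` (mass, dry-mass fraction, radius, initial temperature, GAB
#' parameters), `air`, per-mode `scenario` entries (transfer coefficients,
#' ultrasound power, Arrhenius diffusivity, shrinkage slope), `numerics`
#' and `noise` defaults for the synthetic generators.
#'
#' @return A nested list.
#' @export
default_config <- function() {
  gab <- blackberry_gab_default()
  scen <- lapply(c(none = "none", airborne = "airborne", contact = "contact"),
                 function(m) {
                   arr <- .blackberry_arrhenius[[m]]
                   list(h = .blackberry_h[[m]], h_m = .blackberry_hm[[m]],
                        P_US = .blackberry_P[[m]],
                        D0 = unname(arr[["D0"]]), b = unname(arr[["b"]]),
                        shrinkage_slope = .blackberry_shrinkage_slope[[m]])
                 })
  list(
    material = list(M0 = 3.5e-3, f_dm = 0.138, r0 = 0.0125, T0 = 298.15,
                    gab = list(W_m = gab$W_m, C = gab$C, K = gab$K)),
    air = list(T_air = 338.15, RH = 10, rho_air = 1.029, Cp_air = 1.0e3,
               alpha_air = 2.5e-5, D_air = 2.18e-5),
    scenario = c(scen, list(duration = 6 * 3600)),
    numerics = list(n_nodes = 121L, rtol = 1e-6, atol = 1e-8,
                    output_dt = 10),
    noise = list(kinetics = list(kind = "gaussian_multiplicative",
                                 sigma = 0.02),
                 cooling = list(kind = "gaussian_additive", sigma = 0.2),
                 calorimetry = list(kind = "gaussian_additive", sigma = 0.05),
                 sorption = list(kind = "gaussian_multiplicative",
                                 sigma = 0.03)))
}

#' Read / write a pipeline configuration
#'
#' YAML round-trip of the nested configuration list; [read_config()] fills
#' any missing section from [default_config()].
#'
#' @param path File path.
#' @return For `read_config`, the configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' @rdname read_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build parameter objects from a configuration
#'
#' @param config A configuration list as [default_config()].
#' @param mode Treatment mode.
#' @return `material_from_config()` returns a [material_spec()];
#'   `scenario_from_config()` a [drying_scenario()];
#'   `numerics_from_config()` a [numerics_config()].
#' @export
material_from_config <- function(config, mode = "none") {
  m <- config$material
  s <- config$scenario[[.mode_match(mode)]]
  material_spec(M0 = m$M0, f_dm = m$f_dm, r0 = m$r0,
                gab = gab_params(m$gab$W_m, m$gab$C, m$gab$K),
                arrhenius = arrhenius_params(s$D0, s$b),
                shrinkage = shrinkage_law(s$shrinkage_slope),
                T0 = m$T0)
}

#' @rdname material_from_config
#' @export
scenario_from_config <- function(config, mode = "none") {
  a <- config$air
  s <- config$scenario[[.mode_match(mode)]]
  drying_scenario(air = air_state(a$T_air, a$RH, a$rho_air, a$Cp_air,
                                  a$alpha_air, a$D_air),
                  mode = .mode_match(mode), P_US = s$P_US, h = s$h,
                  h_m = s$h_m, duration = config$scenario$duration)
}

#' @rdname material_from_config
#' @export
numerics_from_config <- function(config) {
  n <- config$numerics
  numerics_config(n_nodes = n$n_nodes, rtol = n$rtol, atol = n$atol,
                  output_dt = n$output_dt)
}
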