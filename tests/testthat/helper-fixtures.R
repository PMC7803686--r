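# Shared fixtures and independent oracles for the test suite.

# Exact volume-average moisture ratio of Fickian diffusion in a sphere with
# a fixed surface concentration (multi-term eigenfunction series).  This is
# the independent analytical oracle for both the PDE solver and the
# slope-method estimator.
mr_series_exact <- function(t, De, r, n_terms = 50L) {
  n <- seq_len(n_terms)
  vapply(t, function(ti)
    sum(6 / (n^2 * pi^2) * exp(-n^2 * pi^2 * De * ti / r^2)),
    numeric(1))
}

# Constant-property material: no shrinkage, temperature-independent
# diffusivity, start at air temperature.
benchmark_material <- function(De = 1.411e-9, r0 = 0.0125,
                               gab = blackberry_gab_default()) {
  material_spec(M0 = 3.5e-3, f_dm = 0.138, r0 = r0, gab = gab,
                arrhenius = arrhenius_params(D0 = De, b = 0),
                shrinkage = shrinkage_law(0), T0 = 338.15)
}

# Surface pinned at the air-equilibrium moisture: enormous transfer
# coefficients make the surface resistance negligible.
benchmark_scenario <- function(duration = 30000) {
  drying_scenario(air_state(338.15, 10), "none", 0, h = 1e7, h_m = 1.0,
                  duration = duration)
}

# Memoized study-condition simulations shared across acceptance checks:
# three drying modes with the published calibration, run until the average
# moisture reaches 1.0 kg/kg DM.
.sim_cache <- new.env(parent = emptyenv())

mode_simulation <- function(mode, n_nodes = 121L) {
  key <- paste0(mode, "_", n_nodes)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_drying(
      blackberry_material(mode),
      blackberry_scenario(mode, duration = 24 * 3600),
      numerics_config(n_nodes = n_nodes),
      stop_at_moisture = 1.0)
  }
  .sim_cache[[key]]
}

# Short runs with dense early output for the surface-center transient.
transient_simulation <- function(mode) {
  key <- paste0("transient_", mode)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_drying(
      blackberry_material(mode),
      blackberry_scenario(mode, duration = 1800),
      numerics_config(n_nodes = 121),
      times = c(seq(0, 5, 0.05), seq(5.5, 60, 0.5), seq(65, 1800, 5)))
  }
  .sim_cache[[key]]
}
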