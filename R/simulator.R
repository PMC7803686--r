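# Coupled heat and mass transfer in a shrinking spherical fruit, solved by
# the method of lines on the normalized radial coordinate xi = x / r(t).
#
# Governing equations (spherically symmetric, internal source Q_e = 0):
#   rho_b Cp dT/dt = (1/x^2) d/dx (x^2 lambda dT/dx)
#   dW/dt          = (1/x^2) d/dx (x^2 De(T) dW/dx)
# Surface balances (J = h_m (C_s - C_air) is the outward evaporative flux):
#   lambda dT/dx|r = h (T_air - T_s) - h_fg J + Q_US,   Q_US = P_US/(4 pi r^2)
#   -rho_s De dW/dx|r = J
# Shrinkage is quasi-static: r follows the volume-average moisture through
# the material's linear shrinkage law, and the grid-velocity advection term
# is neglected.  The spatial operator is a conservative finite-volume
# discretization, so the semi-discrete system conserves water mass exactly;
# the cumulative evaporated mass is co-integrated as a diagnostic state.

#' External drying conditions
#'
#' @param air An [air_state()] object.
#' @param mode Treatment: `"none"`, `"airborne"` or `"contact"`.  Zero
#'   ultrasound power is only consistent with mode `"none"` and vice versa.
#' @param P_US Dissipated ultrasound power reaching the fruit surface (W).
#' @param h Convective heat transfer coefficient (W m^-2 K^-1).
#' @param h_m Convective mass transfer coefficient (m s^-1).
#' @param duration Simulated duration (s).
#' @return An object of class `drying_scenario`.
#' @export
drying_scenario <- function(air, mode = c("none", "airborne", "contact"),
                            P_US = 0, h, h_m, duration) {
  stopifnot(inherits(air, "air_state"))
  mode <- match.arg(mode)
  if ((P_US == 0) != (mode == "none"))
    stop("`P_US` must be 0 exactly when `mode` is \"none\"", call. = FALSE)
  if (P_US < 0) stop("`P_US` must be non-negative", call. = FALSE)
  if (h <= 0 || h_m <= 0)
    stop("`h` and `h_m` must be positive", call. = FALSE)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  structure(list(air = air, mode = mode, P_US = P_US, h = h, h_m = h_m,
                 duration = duration),
            class = "drying_scenario")
}

#' Numerical configuration of the drying solver
#'
#' @param n_nodes Number of radial nodes including center and surface
#'   (default 121, i.e. the radius divided into 120 intervals; >= 11).
#' @param rtol,atol Relative and absolute tolerances of the stiff
#'   integrator.
#' @param output_dt Output cadence in simulated seconds (default 10 s); the
#'   final state is always stored.
#' @param max_steps Maximum internal integrator steps between outputs.
#' @return An object of class `numerics_config`.
#' @export
numerics_config <- function(n_nodes = 121L, rtol = 1e-6, atol = 1e-8,
                            output_dt = 10, max_steps = 50000L) {
  if (n_nodes < 11L) stop("`n_nodes` must be at least 11", call. = FALSE)
  if (rtol <= 0 || atol <= 0)
    stop("tolerances must be positive", call. = FALSE)
  if (output_dt <= 0) stop("`output_dt` must be positive", call. = FALSE)
  structure(list(n_nodes = as.integer(n_nodes), rtol = rtol, atol = atol,
                 output_dt = output_dt, max_steps = as.integer(max_steps)),
            class = "numerics_config")
}

#' Simulate drying of a shrinking spherical fruit
#'
#' Integrates the coupled heat and moisture equations with evaporative and
#' acoustic surface fluxes, GAB-controlled surface water activity,
#' temperature-dependent Arrhenius diffusivity evaluated nodewise, and a
#' radius that follows the volume-average moisture through the material's
#' shrinkage law.
#'
#' @param spec A [material_spec()].
#' @param scenario A [drying_scenario()].
#' @param numerics A [numerics_config()].
#' @param times Optional vector of output times (s); defaults to a uniform
#'   grid at the configured cadence plus the final time.
#' @param stop_at_moisture Optional volume-average moisture (kg/kg DM); if
#'   supplied, integration terminates when the average moisture first
#'   reaches this value.
#' @return An object of class `drying_simulation` with elements `times`,
#'   `xi`, `T` and `W` (time-by-node matrices, K and kg/kg DM), `radius`,
#'   `W_avg`, `T_surface`, `T_center`, `evaporated` (cumulative evaporated
#'   water mass, kg) and the inputs.
#' @export
simulate_drying <- function(spec, scenario, numerics = numerics_config(),
                            times = NULL, stop_at_moisture = NULL) {
  stopifnot(inherits(spec, "material_spec"),
            inherits(scenario, "drying_scenario"),
            inherits(numerics, "numerics_config"))
  N <- numerics$n_nodes
  dxi <- 1 / (N - 1)
  xi <- seq(0, 1, length.out = N)

  # finite-volume cell volumes (xi^2 measure) and interior face areas
  faces <- xi[-N] + dxi / 2                       # xi_{i+1/2}, i = 1..N-1
  edges <- c(0, faces, 1)
  Vcell <- diff(edges^3) / 3
  a_face <- faces^2
  Vsum <- sum(Vcell)                              # = 1/3 exactly

  m_dm <- spec$M0 * spec$f_dm
  W0 <- spec$W0
  r0 <- spec$r0
  slope <- spec$shrinkage$slope
  icpt <- spec$shrinkage$intercept
  D0 <- spec$arrhenius$D0
  b_arr <- spec$arrhenius$b
  gab <- spec$gab
  air <- scenario$air
  h <- scenario$h
  h_m <- scenario$h_m
  P_US <- scenario$P_US
  T_air <- air$T_air
  C_air <- 2.1667e-3 * (air$RH / 100) * .psat(T_air) / T_air

  iT <- seq_len(N)
  iW <- N + seq_len(N)

  rhs <- function(t, y, parms) {
    T <- y[iT]
    W <- pmax(y[iW], 0)
    W_avg <- sum(Vcell * W) / Vsum
    r <- r0 * (icpt + slope * min(max(W_avg, 0), W0) / W0)
    rho_s <- m_dm / (4 / 3 * pi * r^3)

    De <- D0 * exp(-b_arr / T)
    lam <- (0.149 + 0.493 * W) / (1 + W)
    Cp <- (0.837 + 1.256 * W) * 1000
    rho_b <- (1 + W) * rho_s

    Ts <- T[N]
    aw_s <- .gab_aw(W[N], gab)
    if (is.na(aw_s) || aw_s > 0.9999) aw_s <- 0.9999
    Cs <- 2.1667e-3 * aw_s * .psat(Ts) / Ts
    J <- h_m * (Cs - C_air)
    Qus <- P_US / (4 * pi * r^2)
    hfg <- 2501.05e3 * ((647.3 - Ts) / (647.3 - 273.15))^0.3298

    lam_f <- (lam[-1L] + lam[-N]) / 2
    De_f <- (De[-1L] + De[-N]) / 2
    FT <- a_face * lam_f * diff(T) / dxi
    FW <- a_face * De_f * diff(W) / dxi
    FT_surf <- r * (h * (T_air - Ts) - hfg * J + Qus)   # lambda dT/dxi at xi=1
    FW_surf <- -r * J / rho_s                           # De dW/dxi at xi=1

    dT <- (c(FT, FT_surf) - c(0, FT)) / (rho_b * Cp * r^2 * Vcell)
    dW <- (c(FW, FW_surf) - c(0, FW)) / (r^2 * Vcell)
    list(c(dT, dW, 4 * pi * r^2 * J))
  }

  if (is.null(times)) {
    times <- unique(c(seq(0, scenario$duration, by = numerics$output_dt),
                      scenario$duration))
  } else {
    times <- sort(unique(as.numeric(times)))
    if (times[1L] != 0) times <- c(0, times)
  }

  y0 <- c(rep(spec$T0, N), rep(W0, N), 0)
  rootfun <- if (!is.null(stop_at_moisture)) {
    target <- stop_at_moisture
    function(t, y, parms) sum(Vcell * y[iW]) / Vsum - target
  } else NULL

  sol <- deSolve::lsodar(y = y0, times = times, func = rhs, parms = NULL,
                         rtol = numerics$rtol, atol = numerics$atol,
                         rootfunc = rootfun, maxsteps = numerics$max_steps)
  istate <- attr(sol, "istate")[1L]
  if (istate < 0 && istate != 3L)   # 3 = terminated at root
    stop("drying solver failed (istate = ", istate, ") at t = ",
         sol[nrow(sol), 1L], " s; last average moisture = ",
         signif(sum(Vcell * sol[nrow(sol), 1L + iW]) / Vsum, 6),
         call. = FALSE)

  Tm <- unname(sol[, 1L + iT, drop = FALSE])
  Wm <- unname(sol[, 1L + iW, drop = FALSE])
  if (any(Wm < -1e-6))
    stop("invariant breach: negative moisture in the solution", call. = FALSE)
  W_avg <- as.numeric(Wm %*% Vcell) / Vsum
  radius <- r0 * (icpt + slope * pmin(pmax(W_avg, 0), W0) / W0)

  structure(list(times = unname(sol[, 1L]), xi = xi, T = Tm, W = Wm,
                 radius = radius, W_avg = W_avg,
                 T_surface = Tm[, N], T_center = Tm[, 1L],
                 evaporated = unname(sol[, ncol(sol)]),
                 cell_volumes = Vcell, dry_mass = m_dm,
                 spec = spec, scenario = scenario, numerics = numerics),
            class = "drying_simulation")
}

#' @export
print.drying_simulation <- function(x, ...) {
  cat("Drying simulation (", x$scenario$mode, " mode)\n", sep = "")
  cat(sprintf("  %d output times over %.0f s, %d radial nodes\n",
              length(x$times), max(x$times), length(x$xi)))
  cat(sprintf("  W_avg: %.3f -> %.3f kg/kg DM;  radius: %.2f -> %.2f mm\n",
              x$W_avg[1L], x$W_avg[length(x$W_avg)],
              1e3 * x$radius[1L], 1e3 * x$radius[length(x$radius)]))
  invisible(x)
}

#' Volume-average of a radial profile
#'
#' Volume-weighted mean of a profile on the normalized sphere,
#' `int(W xi^2 dxi) / int(xi^2 dxi)`, by the composite trapezoid rule on
#' the node grid.
#'
#' @param profile Values at the nodes.
#' @param xi Normalized node positions in `[0, 1]`, same length.
#' @return The volume-average value.
#' @export
average_moisture <- function(profile, xi) {
  if (length(profile) != length(xi) || length(xi) < 2L)
    stop("`profile` and `xi` must be equal-length vectors (>= 2)",
         call. = FALSE)
  trap <- function(f) sum(diff(xi) * (f[-1L] + f[-length(f)]) / 2)
  trap(profile * xi^2) / trap(xi^2)
}

#' Time at which the average moisture reaches a target
#'
#' Linear interpolation between the bracketing stored samples of the
#' volume-average moisture history.
#'
#' @param result A [simulate_drying()] result.
#' @param W_target Target volume-average moisture (kg water / kg dry
#'   matter), within the range spanned by the simulation.
#' @return Time (s).
#' @export
time_to_moisture <- function(result, W_target) {
  stopifnot(inherits(result, "drying_simulation"))
  W <- result$W_avg
  if (W_target > W[1L] + 1e-12 || W_target < min(W) - 1e-12)
    stop(sprintf("target %.4g not reached: average moisture spans [%.4g, %.4g]",
                 W_target, min(W), W[1L]), call. = FALSE)
  if (W_target >= W[1L]) return(result$times[1L])
  k <- which(W <= W_target)[1L]
  t1 <- result$times[k - 1L]; t2 <- result$times[k]
  w1 <- W[k - 1L]; w2 <- W[k]
  t1 + (w1 - W_target) / (w1 - w2) * (t2 - t1)
}

#' Surface-to-center temperature and moisture differences
#'
#' @param result A [simulate_drying()] result.
#' @return A data.frame with columns `time_s`, `dT` (surface minus center
#'   temperature, K) and `dW` (center minus surface moisture, kg/kg DM).
#' @export
surface_center_difference <- function(result) {
  stopifnot(inherits(result, "drying_simulation"))
  N <- length(result$xi)
  data.frame(time_s = result$times,
             dT = result$T[, N] - result$T[, 1L],
             dW = result$W[, 1L] - result$W[, N])
}

#' Mass-balance residual of a drying simulation
#'
#' Compares the water lost by the fruit, `m_dm * (W_avg(0) - W_avg(t))`,
#' with the co-integrated cumulative evaporated mass at every stored time.
#' The semi-discrete scheme conserves mass exactly, so this residual
#' measures pure time-integration error.
#'
#' @param result A [simulate_drying()] result.
#' @return Maximum absolute mismatch over the stored times, relative to the
#'   total evaporated mass.
#' @export
mass_balance_residual <- function(result) {
  stopifnot(inherits(result, "drying_simulation"))
  lost <- result$dry_mass * (result$W_avg[1L] - result$W_avg)
  denom <- max(abs(result$evaporated), result$dry_mass * result$W_avg[1L] * 1e-9)
  max(abs(lost - result$evaporated)) / denom
}
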