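# Parameter estimation from (synthetic or measured) experimental series:
# GAB isotherm fit, slope-method effective diffusivity, Arrhenius
# regression, lumped-capacitance heat transfer coefficient, Chilton-Colburn
# mass transfer coefficient and calorimetric ultrasound power.

#' Copper calibration sphere
#'
#' The copper sphere used both for the lumped-capacitance estimation of the
#' heat transfer coefficient and for calorimetric ultrasound power
#' measurements (copper density 8.96e3 kg m^-3, specific heat
#' 390 J kg^-1 K^-1, diameter 25 mm).
#'
#' @param diameter Sphere diameter (m).
#' @param rho Copper density (kg m^-3).
#' @param Cp Copper specific heat (J kg^-1 K^-1).
#' @return An object of class `copper_sphere` with derived `radius`, `area`,
#'   `volume` and `mass` elements.
#' @export
copper_sphere <- function(diameter = 0.025, rho = 8.96e3, Cp = 390) {
  if (any(c(diameter, rho, Cp) <= 0))
    stop("all copper sphere parameters must be positive", call. = FALSE)
  radius <- diameter / 2
  volume <- 4 / 3 * pi * radius^3
  structure(list(diameter = diameter, rho = rho, Cp = Cp, radius = radius,
                 area = 4 * pi * radius^2, volume = volume,
                 mass = rho * volume),
            class = "copper_sphere")
}

#' Drying-kinetics series
#'
#' @param time Time (s), strictly increasing, starting at 0.
#' @param moisture Dry-basis moisture (kg water / kg dry matter).
#' @param temperature Drying air temperature label (K), optional.
#' @param mode Treatment tag, optional.
#' @return An object of class `kinetics_series`.
#' @export
kinetics_series <- function(time, moisture, temperature = NA_real_,
                            mode = NA_character_) {
  .check_series_time(time)
  if (length(moisture) != length(time))
    stop("`time` and `moisture` must have equal length", call. = FALSE)
  structure(list(time = as.numeric(time), moisture = as.numeric(moisture),
                 temperature = temperature, mode = mode),
            class = "kinetics_series")
}

#' Copper-sphere cooling (or heating) series
#'
#' @param time Time (s), strictly increasing.
#' @param T_surface Sphere surface temperature (K).
#' @param sphere A [copper_sphere()] object.
#' @return An object of class `cooling_series`.
#' @export
cooling_series <- function(time, T_surface, sphere = copper_sphere()) {
  .check_series_time(time)
  if (length(T_surface) != length(time))
    stop("`time` and `T_surface` must have equal length", call. = FALSE)
  stopifnot(inherits(sphere, "copper_sphere"))
  structure(list(time = as.numeric(time), T_surface = as.numeric(T_surface),
                 sphere = sphere),
            class = "cooling_series")
}

#' Calorimetry series
#'
#' @param time Time (s), strictly increasing.
#' @param temperature Absorber temperature (K).
#' @return An object of class `calorimetry_series`.
#' @export
calorimetry_series <- function(time, temperature) {
  .check_series_time(time)
  if (length(temperature) != length(time))
    stop("`time` and `temperature` must have equal length", call. = FALSE)
  structure(list(time = as.numeric(time), temperature = as.numeric(temperature)),
            class = "calorimetry_series")
}

#' Sorption-equilibrium table
#'
#' Pairs of water activity and equilibrium dry-basis moisture from a
#' static-gravimetric experiment.
#'
#' @param a_w Water activities, each in (0, 1).
#' @param W_eq Equilibrium moistures (kg water / kg dry matter, > 0).
#' @return An object of class `sorption_table` (also a data.frame with
#'   columns `aw`, `weq_db`).
#' @export
sorption_table <- function(a_w, W_eq) {
  if (length(a_w) != length(W_eq))
    stop("`a_w` and `W_eq` must have equal length", call. = FALSE)
  if (any(a_w <= 0) || any(a_w >= 1))
    stop("`a_w` values must lie strictly inside (0, 1)", call. = FALSE)
  if (any(W_eq <= 0))
    stop("`W_eq` values must be positive", call. = FALSE)
  structure(data.frame(aw = as.numeric(a_w), weq_db = as.numeric(W_eq)),
            class = c("sorption_table", "data.frame"))
}

.check_series_time <- function(time) {
  if (length(time) < 2L || any(!is.finite(time)) || any(diff(time) <= 0))
    stop("`time` must be a strictly increasing numeric vector", call. = FALSE)
  invisible(time)
}

#' Goodness-of-fit report
#'
#' @param params Estimated parameter object or named list.
#' @param r_squared Coefficient of determination.
#' @param rmse Root mean square error, in the units of the fitted variable.
#' @param aad_percent Absolute average deviation, percent.
#' @return An object of class `fit_report`.
#' @export
fit_report <- function(params, r_squared, rmse, aad_percent) {
  if (r_squared > 1 + 1e-12) stop("`r_squared` cannot exceed 1", call. = FALSE)
  if (rmse < 0 || aad_percent < 0)
    stop("`rmse` and `aad_percent` must be non-negative", call. = FALSE)
  structure(list(params = params, r_squared = r_squared, rmse = rmse,
                 aad_percent = aad_percent),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Fit report\n")
  cat(sprintf("  R^2 = %.4f, RMSE = %.4g, AAD = %.2f%%\n",
              x$r_squared, x$rmse, x$aad_percent))
  invisible(x)
}

#' Fit the GAB isotherm to sorption-equilibrium data
#'
#' Nonlinear least squares of the GAB isotherm over a deterministic
#' multi-start grid (`W_m` in \{0.05, 0.1, 0.2\}, `C` in \{1, 10, 50\},
#' `K` in \{0.5, 0.7, 0.9\} by default); the start with the lowest final
#' residual sum of squares wins, ties broken by grid order, so repeated
#' fits of the same table are identical.
#'
#' @param table A [sorption_table()] (or data.frame with columns `aw`,
#'   `weq_db`) with at least 5 rows.
#' @param start_grid Data frame of starting values with columns `W_m`, `C`,
#'   `K`.
#' @return A list with elements `params` ([gab_params()]) and `report`
#'   ([fit_report()]).
#' @export
fit_gab <- function(table,
                    start_grid = expand.grid(W_m = c(0.05, 0.1, 0.2),
                                             C = c(1, 10, 50),
                                             K = c(0.5, 0.7, 0.9))) {
  if (!all(c("aw", "weq_db") %in% names(table)))
    stop("`table` must have columns `aw` and `weq_db`", call. = FALSE)
  if (nrow(table) < 5L)
    stop("at least 5 sorption points are needed for a 3-parameter fit",
         call. = FALSE)
  dat <- data.frame(aw = table$aw, weq = table$weq_db)
  best <- NULL
  best_ssr <- Inf
  for (i in seq_len(nrow(start_grid))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        weq ~ W_m * C * K * aw / ((1 - K * aw) * (1 - K * aw + C * K * aw)),
        data = dat,
        start = as.list(start_grid[i, , drop = TRUE]),
        lower = c(W_m = 1e-8, C = 1e-8, K = 1e-6),
        upper = c(W_m = Inf, C = Inf, K = 0.9999),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(stats::resid(fit)^2)
    if (!is.finite(ssr)) next
    if (ssr < best_ssr) {     # strict: ties keep the earlier grid start
      best <- fit
      best_ssr <- ssr
    }
  }
  if (is.null(best))
    stop("GAB fit failed to converge from any of the ", nrow(start_grid),
         " grid starts", call. = FALSE)
  cf <- stats::coef(best)
  params <- gab_params(W_m = cf[["W_m"]], C = cf[["C"]], K = cf[["K"]])
  m <- fit_metrics(predicted = stats::fitted(best), observed = dat$weq)
  list(params = params,
       report = fit_report(params, m$r_squared, m$rmse, m$aad_percent))
}

#' Effective diffusivity by the slope method
#'
#' Fits the one-term truncation of the exact sphere-diffusion series,
#' \deqn{MR = \frac{W - W_{eq}}{W_0 - W_{eq}} = \frac{6}{\pi^2}
#'   \exp\!\left(-\frac{D_e \pi^2}{r^2} t\right),}
#' by ordinary least squares of `log(MR)` against time, retaining only the
#' points where the one-term series dominates (moisture ratio below
#' `mr_threshold`, t > 0).  `De = -slope * r^2 / pi^2`.
#'
#' @param series A [kinetics_series()].
#' @param r Sphere radius (m).
#' @param W_eq Equilibrium moisture; defaults to the mean of the last three
#'   series points.
#' @param mr_threshold Retain points with moisture ratio strictly below
#'   this value (default 0.6).
#' @return Effective diffusivity (m^2 s^-1).
#' @export
estimate_de_slope <- function(series, r, W_eq = NULL, mr_threshold = 0.6) {
  stopifnot(inherits(series, "kinetics_series"))
  if (r <= 0) stop("`r` must be positive", call. = FALSE)
  W <- series$moisture
  t <- series$time
  if (max(W) - min(W) <= 0)
    stop("constant-moisture series: no drying signal to fit", call. = FALSE)
  if (is.null(W_eq)) W_eq <- mean(utils::tail(W, 3L))
  W0 <- W[1L]
  mr <- (W - W_eq) / (W0 - W_eq)
  keep <- t > 0 & mr < mr_threshold
  if (any(keep & mr <= 0))
    stop("retained moisture ratios include non-positive values; ",
         "supply a smaller `W_eq`", call. = FALSE)
  if (sum(keep) < 2L)
    stop("fewer than 2 points fall below the moisture-ratio threshold ",
         mr_threshold, call. = FALSE)
  slope <- stats::coef(stats::lm(log(mr[keep]) ~ t[keep]))[[2L]]
  if (slope >= 0)
    warning("non-negative log-moisture slope; returning De = 0",
            call. = FALSE)
  max(-slope, 0) * r^2 / pi^2
}

#' Arrhenius regression of effective diffusivities
#'
#' Linear regression of `log(De)` against `1/T`; the pre-exponential factor
#' is `exp(intercept)` and the activation temperature `b = -slope`.
#'
#' @param temperature Temperatures (K), at least two distinct values.
#' @param De Effective diffusivities (m^2 s^-1), same length.
#' @return An [arrhenius_params()] object.
#' @export
fit_arrhenius <- function(temperature, De) {
  if (length(temperature) != length(De))
    stop("`temperature` and `De` must have equal length", call. = FALSE)
  if (length(unique(temperature)) < 2L)
    stop("at least two distinct temperatures are required", call. = FALSE)
  if (any(De <= 0)) stop("`De` values must be positive", call. = FALSE)
  cf <- stats::coef(stats::lm(log(De) ~ I(1 / temperature)))
  arrhenius_params(D0 = exp(cf[[1L]]), b = -cf[[2L]])
}

#' Heat transfer coefficient by the lumped-capacitance method
#'
#' Fits the exponential temperature response of a sphere with negligible
#' internal gradients,
#' \deqn{\frac{T - T_{air}}{T_0 - T_{air}} =
#'   \exp\!\left(-\frac{h A}{\rho C_p V} t\right),}
#' by nonlinear least squares in `h` (for a sphere `A/V = 3/radius`).
#'
#' @param series A [cooling_series()].
#' @param T_air Air temperature (K).
#' @param T0 Initial sphere temperature (K); defaults to the first sample.
#' @return A list with elements `h` (W m^-2 K^-1) and `report`
#'   ([fit_report()]).
#' @export
fit_h_lumped <- function(series, T_air, T0 = NULL) {
  stopifnot(inherits(series, "cooling_series"))
  if (length(series$time) < 5L)
    stop("at least 5 points are required", call. = FALSE)
  if (is.null(T0)) T0 <- series$T_surface[1L]
  if (abs(T0 - T_air) <= 1)
    stop("|T0 - T_air| must exceed 1 K for an identifiable decay",
         call. = FALSE)
  sph <- series$sphere
  k_geom <- 3 / (sph$rho * sph$Cp * sph$radius)   # A/(rho Cp V) for a sphere
  dat <- data.frame(t = series$time, Ts = series$T_surface)
  # log-linear starting value, guarded for noisy sign flips
  theta <- (dat$Ts - T_air) / (T0 - T_air)
  ok <- theta > 0 & dat$t > 0
  h_start <- if (sum(ok) >= 2L)
    max(-stats::coef(stats::lm(log(theta[ok]) ~ dat$t[ok]))[[2L]] / k_geom, 1)
  else 20
  fit <- tryCatch(
    minpack.lm::nlsLM(Ts ~ T_air + (T0 - T_air) * exp(-h * k_geom * t),
                      data = dat, start = list(h = h_start),
                      lower = c(h = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("lumped-capacitance fit failed to converge: ",
           conditionMessage(e), call. = FALSE))
  h <- stats::coef(fit)[["h"]]
  m <- fit_metrics(predicted = stats::fitted(fit), observed = dat$Ts)
  list(h = h, report = fit_report(list(h = h), m$r_squared, m$rmse,
                                  m$aad_percent))
}

#' Mass transfer coefficient from the Chilton-Colburn analogy
#'
#' `h_m = h * Le^(2/3) / (rho_air * Cp_air)` with Lewis number
#' `Le = alpha_air / D_air`.  This is the orientation of the analogy that
#' reproduces the published coefficient pairs for this dryer; see the
#' methods vignette for the relation to the textbook form.
#'
#' @param h Heat transfer coefficient (W m^-2 K^-1).
#' @param air An [air_state()] object.
#' @return Mass transfer coefficient (m s^-1).
#' @export
hm_from_h <- function(h, air) {
  stopifnot(inherits(air, "air_state"))
  Le <- air$alpha_air / air$D_air
  h * Le^(2 / 3) / (air$rho_air * air$Cp_air)
}

#' Ultrasound power by calorimetry
#'
#' Ordinary least-squares slope of the initial linear temperature rise of
#' an insulated absorber sphere; `P = m * Cp * dT/dt`.
#'
#' @param series A [calorimetry_series()].
#' @param sphere A [copper_sphere()] absorber.
#' @param window_s Fit window: the first `window_s` seconds or the first
#'   `min_points` samples, whichever spans more points (default 60 s / 10
#'   points).
#' @param min_points See `window_s`.
#' @return Dissipated ultrasound power (W).
#' @export
calorimetric_power <- function(series, sphere = copper_sphere(),
                               window_s = 60, min_points = 10L) {
  stopifnot(inherits(series, "calorimetry_series"),
            inherits(sphere, "copper_sphere"))
  t <- series$time
  n_window <- max(sum(t <= t[1L] + window_s), min(min_points, length(t)))
  if (n_window < 3L)
    stop("at least 3 points are required in the calorimetry window",
         call. = FALSE)
  idx <- seq_len(n_window)
  slope <- stats::coef(stats::lm(series$temperature[idx] ~ t[idx]))[[2L]]
  if (slope <= 0)
    stop("no heating detected: fitted temperature slope is not positive",
         call. = FALSE)
  sphere$mass * sphere$Cp * slope
}

#' Acoustic intensity on a spherical surface
#'
#' Spreads a dissipated power over the sphere area, `Q_US = P / (4 pi r^2)`.
#' As the fruit shrinks the same power concentrates on a smaller surface,
#' so the intensity grows.
#'
#' @param P Dissipated ultrasound power (W, >= 0).
#' @param r Sphere radius (m, > 0).
#' @return Surface intensity (W m^-2).
#' @export
ultrasound_intensity <- function(P, r) {
  if (any(P < 0)) stop("`P` must be non-negative", call. = FALSE)
  if (any(r <= 0)) stop("`r` must be positive", call. = FALSE)
  P / (4 * pi * r^2)
}
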