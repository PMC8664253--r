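#' Lumped model of thermal-diffusivity-limited one-sided sample cooling
#'
#' A thin aqueous sample of effective depth `thickness` is cooled from one
#' surface (the heat exchanger). Heat flow through the water column,
#' dQ/dt = -kappa A dT / L, combined with Q = c m T gives a single
#' exponential relaxation with rate constant k = kappa A / (c m L):
#' T(t) = dT (exp(-k t) - 1) + T0.
#'
#' The heat capacity is given volumetrically (J cm^-3 K^-1) as is customary
#' for water; with the default mass convention m = rho A L the model is
#' density-free and the rate constant reduces to kappa / (c_vol L^2).
#'
#' @param thickness Effective depth L of the sample (m).
#' @param area Cooled surface area (m^2). Default 2e-5 m^2 (4-mm cover slide).
#' @param kappa Thermal conductivity of water (W m^-1 K^-1). Default 0.5562.
#' @param c_vol Volumetric heat capacity (J cm^-3 K^-1). Default 4 (water).
#' @param t0 Initial sample temperature (degrees C). Default 37.
#' @param coolant Coolant temperature (degrees C). Default -196 (liquid
#'   nitrogen); the initial difference delta_T = t0 - coolant.
#' @param mass Sample mass (kg). Default `NULL`, meaning rho A L with
#'   `density`; pass a value to override (e.g. the nominal 0.25 mg).
#' @param density Water density (kg/m^3) used when `mass` is `NULL`.
#' @return An object of class `cooling_model`.
#' @examples
#' m <- cooling_model(thickness = 50e-6)
#' cooling_rate(m, 0)        # ~ 13,000 degrees C/s
#' temperature_course(m, 0.01)
#' @export
cooling_model <- function(thickness, area = 2e-5, kappa = 0.5562, c_vol = 4,
                          t0 = 37, coolant = -196, mass = NULL,
                          density = 1000) {
  stopifnot(thickness > 0, area > 0, kappa > 0, c_vol > 0, density > 0,
            t0 > coolant)
  if (is.null(mass)) mass <- density * area * thickness
  if (mass <= 0) stop("'mass' must be positive")
  c_mass <- c_vol * 1e6 / density            # J kg^-1 K^-1
  k <- kappa * area / (c_mass * mass * thickness)
  structure(list(thickness = thickness, area = area, kappa = kappa,
                 c_vol = c_vol, mass = mass, density = density,
                 t0 = t0, coolant = coolant, delta_T = t0 - coolant,
                 rate_constant = k),
            class = "cooling_model")
}

#' Temperature course of the cooling model
#'
#' T(t) = delta_T (exp(-k t) - 1) + T0: starts at `t0`, relaxes
#' monotonically towards the coolant temperature.
#'
#' @param model A [cooling_model()].
#' @param t Time(s) since the onset of cooling (s), >= 0.
#' @return Temperature (degrees C), vectorized over `t`.
#' @export
temperature_course <- function(model, t) {
  stopifnot(inherits(model, "cooling_model"))
  if (any(t < 0)) stop("'t' must be >= 0")
  model$delta_T * (exp(-model$rate_constant * t) - 1) + model$t0
}

#' Instantaneous cooling rate
#'
#' |dT/dt| = k delta_T exp(-k t); maximal at t = 0, where it equals
#' kappa A delta_T / (c m L).
#'
#' @inheritParams temperature_course
#' @return Cooling rate (degrees C per second, positive), vectorized.
#' @export
cooling_rate <- function(model, t) {
  stopifnot(inherits(model, "cooling_model"))
  if (any(t < 0)) stop("'t' must be >= 0")
  model$rate_constant * model$delta_T * exp(-model$rate_constant * t)
}

#' Time at which the model reaches a given temperature
#'
#' Closed-form inverse of [temperature_course()].
#'
#' @inheritParams temperature_course
#' @param temperature Target temperature (degrees C), in
#'   (coolant, t0].
#' @return Time (s).
#' @export
time_to_temperature <- function(model, temperature) {
  stopifnot(inherits(model, "cooling_model"))
  if (any(temperature > model$t0) || any(temperature <= model$coolant))
    stop("'temperature' must lie in (coolant, t0]")
  frac <- (temperature - model$t0 + model$delta_T) / model$delta_T
  -log(frac) / model$rate_constant
}

#' Mean cooling rate over a temperature interval
#'
#' The interval of interest in vitrification is 0 to -130 degrees C, where
#' ice crystallization can occur. The mean rate is the temperature drop
#' divided by the model time needed to traverse it.
#'
#' @inheritParams temperature_course
#' @param t_hi,t_lo Upper and lower interval temperatures (degrees C),
#'   with coolant < t_lo < t_hi <= t0.
#' @return Mean cooling rate (degrees C per second, positive).
#' @export
interval_mean_rate <- function(model, t_hi, t_lo) {
  stopifnot(inherits(model, "cooling_model"))
  if (!(t_lo < t_hi)) stop("'t_lo' must be below 't_hi'")
  if (t_hi > model$t0 || t_lo <= model$coolant)
    stop("temperatures outside the reachable range (coolant, t0]")
  (t_hi - t_lo) /
    (time_to_temperature(model, t_lo) - time_to_temperature(model, t_hi))
}

#' @export
print.cooling_model <- function(x, ...) {
  cat("One-sided lumped cooling model\n")
  cat(sprintf("  L = %.3g um, A = %.3g m^2, kappa = %.4g W/m/K, c = %.3g J/cm^3/K\n",
              x$thickness * 1e6, x$area, x$kappa, x$c_vol))
  cat(sprintf("  m = %.3g mg, T0 = %.4g C -> coolant %.4g C (delta_T = %.4g C)\n",
              x$mass * 1e6, x$t0, x$coolant, x$delta_T))
  cat(sprintf("  rate constant k = %.4g /s; initial rate %.4g C/s\n",
              x$rate_constant, cooling_rate(x, 0)))
  invisible(x)
}

#' Predicted temperature trace
#'
#' @param object A [cooling_model()].
#' @param times Times (s) at which to evaluate; default 200 points covering
#'   5 relaxation times.
#' @param ... Unused.
#' @return A data.frame with `time_s`, `temperature_C` and `rate_C_per_s`.
#' @export
predict.cooling_model <- function(object, times = NULL, ...) {
  if (is.null(times))
    times <- seq(0, 5 / object$rate_constant, length.out = 200L)
  data.frame(time_s = times,
             temperature_C = temperature_course(object, times),
             rate_C_per_s = cooling_rate(object, times))
}

#' @export
plot.cooling_model <- function(x, ...) {
  tr <- predict(x)
  graphics::plot(tr$time_s * 1e3, tr$temperature_C, type = "l",
                 xlab = "time (ms)", ylab = "temperature (C)",
                 main = "Diffusivity-limited cooling", ...)
  graphics::abline(h = x$coolant, lty = 3)
  invisible(tr)
}
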