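#' DPD unit system
#'
#' Construct the set of base and derived units that map dimensionless DPD
#' quantities onto physical (SI) quantities. The three base units are the
#' cut-off length `l` (metres), the thermal energy `E = k_B T` (joules) and
#' the particle mass `m` (kilograms); time, force and velocity units follow
#' from them:
#' \deqn{t = l \sqrt{m/E}, \quad F = E/l, \quad V = l/t.}
#'
#' The defaults correspond to a plasma-like DPD fluid with a 5 micron
#' cut-off radius at body temperature (k_B T at 300 K), for which the
#' derived time unit is about 15.86 ms and the velocity unit 0.32 mm/s.
#'
#' @param length Base length unit in metres (the cut-off radius).
#' @param energy Base energy unit in joules (k_B T).
#' @param mass Base mass unit in kilograms (rho * l^3 / n_s for fluid
#'   number density n_s).
#' @return An object of class `dpd_units`: a list with elements `length`,
#'   `energy`, `mass`, `time`, `force`, `velocity` (all SI).
#' @examples
#' u <- dpd_units()
#' u$time * 1e3   # ms per DPD time unit
#' to_physical(120, "rate", u)  # bond detachment rate in 1/s
#' @export
dpd_units <- function(length = 5e-6, energy = 4.14e-21, mass = 4.17e-14) {
  if (!is.numeric(length) || length(length) != 1L || !is.finite(length) || length <= 0)
    stop("'length' must be a single positive number", call. = FALSE)
  if (!is.numeric(energy) || length(energy) != 1L || !is.finite(energy) || energy <= 0)
    stop("'energy' must be a single positive number", call. = FALSE)
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) || mass <= 0)
    stop("'mass' must be a single positive number", call. = FALSE)
  tu <- length * sqrt(mass / energy)
  structure(
    list(
      length = length,
      energy = energy,
      mass = mass,
      time = tu,
      force = energy / length,
      velocity = length / tu
    ),
    class = "dpd_units"
  )
}

#' @export
print.dpd_units <- function(x, ...) {
  cat("DPD unit system\n")
  cat(sprintf("  length   : %.4g m\n", x$length))
  cat(sprintf("  energy   : %.4g J\n", x$energy))
  cat(sprintf("  mass     : %.4g kg\n", x$mass))
  cat(sprintf("  time     : %.4g s\n", x$time))
  cat(sprintf("  force    : %.4g N\n", x$force))
  cat(sprintf("  velocity : %.4g m/s\n", x$velocity))
  invisible(x)
}

.unit_factor <- function(dimension, u) {
  switch(dimension,
    length = u$length,
    time = u$time,
    mass = u$mass,
    energy = u$energy,
    force = u$force,
    velocity = u$velocity,
    rate = 1 / u$time,
    stop("unknown unit dimension '", dimension, "'", call. = FALSE)
  )
}

#' Convert between DPD and physical units
#'
#' `to_physical()` maps a dimensionless DPD value to SI units;
#' `to_dpd()` is its inverse. Rates (1/time) convert by division by the
#' time unit, so a DPD detachment rate of 120 becomes about 7566 per
#' second under the default unit system.
#'
#' @param x Numeric vector of values to convert.
#' @param dimension One of `"length"`, `"time"`, `"mass"`, `"energy"`,
#'   `"force"`, `"velocity"`, `"rate"`.
#' @param units A [dpd_units()] object.
#' @return Numeric vector of converted values.
#' @export
to_physical <- function(x, dimension, units = dpd_units()) {
  stopifnot(inherits(units, "dpd_units"))
  x * .unit_factor(match.arg(dimension,
    c("length", "time", "mass", "energy", "force", "velocity", "rate")), units)
}

#' @rdname to_physical
#' @export
to_dpd <- function(x, dimension, units = dpd_units()) {
  stopifnot(inherits(units, "dpd_units"))
  x / .unit_factor(match.arg(dimension,
    c("length", "time", "mass", "energy", "force", "velocity", "rate")), units)
}

#' Microchannel flow specification
#'
#' Bundle the physical parameters of pressure- or pump-driven flow through
#' a rectangular microchannel, from which the analytic plane-Poiseuille
#' reference quantities are computed by [analytic_channel_flow()].
#'
#' @param flow_rate Volumetric flow rate in m^3/s.
#' @param height Channel height H in metres (wall-normal direction).
#' @param width Channel width W in metres.
#' @param density Fluid density in kg/m^3.
#' @param kinematic_viscosity Kinematic viscosity in m^2/s.
#' @param length_scale Characteristic length for the Reynolds number, in
#'   metres (defaults to the DPD cut-off radius, 5 microns).
#' @return An object of class `channel_flow_spec`.
#' @export
channel_flow_spec <- function(flow_rate, height, width,
                              density = 1000, kinematic_viscosity = 1e-6,
                              length_scale = 5e-6) {
  vals <- c(flow_rate = flow_rate, height = height, width = width,
            density = density, kinematic_viscosity = kinematic_viscosity,
            length_scale = length_scale)
  if (any(!is.finite(vals)))
    stop("all channel flow parameters must be finite", call. = FALSE)
  if (flow_rate < 0)
    stop("'flow_rate' must be non-negative", call. = FALSE)
  if (any(vals[-1] <= 0))
    stop("channel geometry and fluid properties must be positive", call. = FALSE)
  structure(as.list(vals), class = "channel_flow_spec")
}

#' Analytic plane-Poiseuille reference values
#'
#' For laminar flow between parallel plates separated by H (width W much
#' larger than H), the mean velocity is Q/(H W), the centreline maximum is
#' 3/2 the mean, the wall shear rate is 4 U_max / H, and the Reynolds
#' number is rho U_avg L / mu with mu = rho nu. These are the reference
#' values the body-force-driven DPD channel flow is calibrated against.
#'
#' @param spec A [channel_flow_spec()].
#' @return A list with `mean_velocity` and `max_velocity` (m/s),
#'   `wall_shear_rate` (1/s) and `reynolds` (dimensionless).
#' @examples
#' spec <- channel_flow_spec(flow_rate = 0.1e-6 / 60, height = 1e-4, width = 2e-3)
#' analytic_channel_flow(spec)
#' @export
analytic_channel_flow <- function(spec) {
  stopifnot(inherits(spec, "channel_flow_spec"))
  u_mean <- spec$flow_rate / (spec$height * spec$width)
  u_max <- 1.5 * u_mean
  mu <- spec$density * spec$kinematic_viscosity
  list(
    mean_velocity = u_mean,
    max_velocity = u_max,
    wall_shear_rate = 4 * u_max / spec$height,
    reynolds = spec$density * u_mean * spec$length_scale / mu
  )
}
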