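#' Wilhelmy wire geometry
#'
#' Geometry and material constants of the partially immersed sensing wire.
#' The defaults `wire_density = 0` and `immersion_depth = 0` drop the
#' weight and buoyancy terms of the force balance, leaving the common
#' simplified reading `F = 2 gamma pi r cos(theta)`.
#'
#' @param radius Wire radius in m (> 0).
#' @param length Wire length in m (> 0).
#' @param wire_density Wire material density in kg/m^3 (>= 0).
#' @param contact_angle Contact angle in radians, in `[0, pi/2)`. A clean
#'   platinum wire is fully wetted (`contact_angle = 0`).
#' @param immersion_depth Depth of the immersed wire segment in m (>= 0).
#' @return A list of class `wire_geometry`.
#' @export
wire_geometry <- function(radius, length, wire_density = 0,
                          contact_angle = 0, immersion_depth = 0) {
  if (radius <= 0) stop("`radius` must be positive", call. = FALSE)
  if (length <= 0) stop("`length` must be positive", call. = FALSE)
  if (wire_density < 0) stop("`wire_density` must be >= 0", call. = FALSE)
  if (contact_angle < 0 || contact_angle >= pi / 2) {
    stop("`contact_angle` must lie in [0, pi/2)", call. = FALSE)
  }
  if (immersion_depth < 0) stop("`immersion_depth` must be >= 0", call. = FALSE)
  structure(list(radius = radius, length = length,
                 wire_density = wire_density, contact_angle = contact_angle,
                 immersion_depth = immersion_depth),
            class = "wire_geometry")
}

#' Subphase properties
#'
#' @param liquid_density Subphase density in kg/m^3 (default water at
#'   25 C, 997).
#' @param clean_surface_tension Surface tension of the clean subphase
#'   gamma_0 in mN/m (default 72.8, water at 25 C).
#' @param g Gravitational acceleration in m/s^2.
#' @return A list of class `subphase_props`.
#' @export
subphase_props <- function(liquid_density = 997,
                           clean_surface_tension = 72.8,
                           g = 9.80665) {
  if (liquid_density <= 0) stop("`liquid_density` must be positive",
                                call. = FALSE)
  if (clean_surface_tension <= 0) {
    stop("`clean_surface_tension` must be positive", call. = FALSE)
  }
  structure(list(liquid_density = liquid_density,
                 clean_surface_tension = clean_surface_tension, g = g),
            class = "subphase_props")
}

#' Net force on a Wilhelmy wire from the surface tension
#'
#' Force balance for a thin wire of radius r and length l partially
#' immersed to depth h in a subphase of density rho_l, with wire density
#' rho_g and contact angle theta:
#'
#'   F = rho_g g pi r^2 l + 2 gamma pi r cos(theta) - rho_l pi r^2 h
#'
#' with gamma converted from mN/m to N/m. The weight and immersion terms
#' are retained as written; with the default geometry (zero wire density
#' and immersion depth) only the wetting term remains.
#'
#' @param gamma Surface tension in mN/m (>= 0, vectorised).
#' @param geom A [wire_geometry()].
#' @param sub A [subphase_props()].
#' @return Net force in N.
#' @examples
#' g <- wire_geometry(radius = 2.5e-4, length = 1e-2)
#' s <- subphase_props()
#' force_from_tension(72, g, s)  # 2 * 0.072 * pi * 2.5e-4 N
#' @export
force_from_tension <- function(gamma, geom, sub) {
  stopifnot(inherits(geom, "wire_geometry"), inherits(sub, "subphase_props"))
  if (any(gamma < 0)) stop("`gamma` must be >= 0", call. = FALSE)
  r <- geom$radius
  geom$wire_density * sub$g * pi * r^2 * geom$length +
    2 * (gamma / 1000) * pi * r * cos(geom$contact_angle) -
    sub$liquid_density * pi * r^2 * geom$immersion_depth
}

#' Surface tension from the net force on a Wilhelmy wire
#'
#' Algebraic inverse of [force_from_tension()]:
#' `gamma = (F - weight + immersion) / (2 pi r cos theta)`, returned in
#' mN/m. The round trip `tension_from_force(force_from_tension(x))`
#' reproduces `x` to better than 10 significant digits.
#'
#' @param force Net force in N (vectorised).
#' @param geom A [wire_geometry()].
#' @param sub A [subphase_props()].
#' @return Surface tension in mN/m.
#' @export
tension_from_force <- function(force, geom, sub) {
  stopifnot(inherits(geom, "wire_geometry"), inherits(sub, "subphase_props"))
  ct <- cos(geom$contact_angle)
  if (ct < 1e-12) {
    stop("degenerate geometry: contact angle too close to pi/2", call. = FALSE)
  }
  r <- geom$radius
  weight <- geom$wire_density * sub$g * pi * r^2 * geom$length
  immersion <- sub$liquid_density * pi * r^2 * geom$immersion_depth
  1000 * (force - weight + immersion) / (2 * pi * r * ct)
}

#' Surface pressure from surface tension
#'
#' The surface pressure of a film is the reduction of the clean subphase's
#' surface tension: `pi = gamma_0 - gamma`. Slightly negative values occur
#' on noisy baselines and are retained (a warning is emitted when the
#' magnitude stays within the cleanliness bound, see [qc_cleanliness()]);
#' set `clamp = TRUE` to floor at zero.
#'
#' @param gamma Measured surface tension in mN/m (vectorised).
#' @param gamma0 Clean-surface tension gamma_0 in mN/m (default 72.8).
#' @param clamp If `TRUE`, negative pressures are set to 0.
#' @return Surface pressure in mN/m.
#' @export
pressure_from_tension <- function(gamma, gamma0 = 72.8, clamp = FALSE) {
  p <- gamma0 - gamma
  if (any(p < 0)) {
    if (clamp) {
      p[p < 0] <- 0
    } else {
      warning(sprintf("%d negative surface pressure value(s) retained (min %.3g mN/m)",
                      sum(p < 0), min(p)), call. = FALSE)
    }
  }
  p
}

#' Subphase cleanliness check
#'
#' Before spreading a film, the clean subphase surface is compressed and
#' the surface-pressure excursion recorded; the surface counts as clean
#' when the excursion does not exceed a small bound (default 0.30 mN/m).
#'
#' @param pressure Surface-pressure signal of the blank compression, mN/m.
#' @param threshold Maximum tolerated |pressure| in mN/m (default 0.30).
#' @return A list with `clean` (logical), `max_abs` (mN/m) and the
#'   threshold used.
#' @export
qc_cleanliness <- function(pressure, threshold = 0.30) {
  m <- max(abs(pressure))
  list(clean = m <= threshold, max_abs = m, threshold = threshold)
}
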