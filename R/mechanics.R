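#' Second moment of area of the circular cross-section
#'
#' For a circular section of diameter d, I = pi * d^4 / 64. This is the
#' geometric stiffness term of Euler column theory; its fourth-power
#' dependence on diameter is why small manufacturing variations in d
#' dominate the buckling force.
#'
#' @param geometry A [monofilament()] object.
#' @return Second moment of area in m^4.
#' @examples
#' second_moment_area(monofilament(0.61, 38))  # 6.797e-15 m^4
#' @export
second_moment_area <- function(geometry) {
  stopifnot(inherits(geometry, "monofilament"))
  pi * geometry$diameter^4 / 64
}

#' Effective column length
#'
#' Le = k * L, where the effective-length factor k encodes the end
#' supports (0.7 clamped-pinned, 2.0 clamped with a sliding pinned end).
#'
#' @param geometry A [monofilament()] object.
#' @param bc A [boundary_condition()], preset name, or bare numeric k.
#' @return Effective length in metres.
#' @examples
#' effective_length(monofilament(0.61, 38), "clamped_pinned")  # 0.0266 m
#' @export
effective_length <- function(geometry, bc = boundary_condition("clamped_pinned")) {
  stopifnot(inherits(geometry, "monofilament"))
  bc <- as_boundary_condition(bc)
  bc$k * geometry$length
}

#' Slenderness ratio of the filament
#'
#' Effective length divided by the radius of gyration of the circular
#' section (d/4). Euler theory assumes a slender column; ratios below 30
#' trigger a validity warning in [critical_buckling_force()].
#'
#' @inheritParams effective_length
#' @return Dimensionless slenderness ratio.
#' @export
slenderness_ratio <- function(geometry, bc = boundary_condition("clamped_pinned")) {
  effective_length(geometry, bc) / (geometry$diameter / 4)
}

#' Euler critical buckling force
#'
#' The axial load at which the filament buckles:
#' Fc = pi^2 * E * I / Le^2, with I = pi * d^4 / 64 and Le = k * L.
#' This is the force the monofilament is designed to deliver to the skin:
#' once buckling starts, pushing further does not increase the applied
#' force appreciably.
#'
#' @param geometry A [monofilament()] object.
#' @param young_modulus Young's modulus in Pa, or a [material_properties()]
#'   object.
#' @param bc A [boundary_condition()], preset name, or bare numeric k.
#' @param warn_slender Emit a warning when the slenderness ratio is below
#'   30 (Euler validity); the value is still returned.
#' @return Critical force in newtons. Use [newton_to_gramforce()] for gf.
#'
#' @examples
#' fc <- critical_buckling_force(monofilament(0.61, 38), 2e9)
#' newton_to_gramforce(fc)  # 19.33 gf: well above the 10 gf rating
#' @export
critical_buckling_force <- function(geometry, young_modulus,
                                    bc = boundary_condition("clamped_pinned"),
                                    warn_slender = TRUE) {
  E <- as_modulus_pa(young_modulus)
  if (!is.finite(E) || E <= 0)
    stop("young_modulus must be positive", call. = FALSE)
  bc <- as_boundary_condition(bc)
  if (warn_slender) {
    sl <- slenderness_ratio(geometry, bc)
    if (sl < 30)
      warning(sprintf(
        "slenderness ratio %.1f < 30: Euler buckling theory may not apply", sl))
  }
  pi^2 * E * second_moment_area(geometry) / effective_length(geometry, bc)^2
}

#' Inverse modulus estimate from a measured buckling force
#'
#' Exact algebraic inverse of [critical_buckling_force()]:
#' E = Fc * Le^2 / (pi^2 * I). Given the measured critical force of a
#' filament of known geometry, this recovers the Young's modulus of its
#' (usually undeclared) material.
#'
#' @param geometry A [monofilament()] object.
#' @param critical_force Measured critical force (> 0).
#' @param bc Boundary condition under which the force was measured;
#'   defaults to clamped-pinned (k = 0.7), the bench calibration setup.
#' @param units Unit of `critical_force`: `"N"` (default) or `"gf"`.
#' @return Young's modulus in Pa.
#'
#' @examples
#' estimate_young_modulus(monofilament(0.46, 41), 9.80, units = "gf") / 1e9
#' # 3.65 GPa
#' @export
estimate_young_modulus <- function(geometry, critical_force,
                                   bc = boundary_condition("clamped_pinned"),
                                   units = c("N", "gf")) {
  units <- match.arg(units)
  stopifnot(is.numeric(critical_force), length(critical_force) == 1L)
  f <- if (units == "gf") gramforce_to_newton(critical_force) else critical_force
  if (!is.finite(f) || f <= 0)
    stop("critical_force must be positive", call. = FALSE)
  f * effective_length(geometry, bc)^2 / (pi^2 * second_moment_area(geometry))
}

#' Environmental corrections to the Young's modulus
#'
#' Nylon softens with temperature and with absorbed moisture. Both effects
#' are modelled as first-order linear corrections about a reference state:
#' E(T) = E0 * (1 - alpha * (T - T0)) and E(H) = E0 * (1 - beta * (H - H0)).
#' `modulus_at_environment()` applies both as a multiplicative composition
#' E0 * (1 - alpha*dT) * (1 - beta*dH), which reduces to either single
#' correction when the other coefficient is zero and is first-order
#' consistent with applying them separately.
#'
#' @param material A [material_properties()] object carrying the relevant
#'   coefficient(s) and reference value(s); missing coefficients are a
#'   configuration error.
#' @param temperature Temperature in degC.
#' @param humidity Relative humidity in %RH.
#' @param conditions An [ambient_conditions()] object.
#' @return Corrected Young's modulus in Pa. A non-positive result (the
#'   linear model pushed outside its validity range) is an error.
#'
#' @examples
#' m <- material_properties(2, temp_coefficient = 0.005, ref_temperature = 20)
#' modulus_at_temperature(m, 30) / 1e9  # 1.9 GPa
#' @export
modulus_at_temperature <- function(material, temperature) {
  stopifnot(inherits(material, "material_properties"),
            is.numeric(temperature), length(temperature) == 1L)
  if (is.null(material$temp_coefficient) || is.null(material$ref_temperature))
    stop("material has no temperature coefficient / reference temperature",
         call. = FALSE)
  E <- material$young_modulus *
    (1 - material$temp_coefficient * (temperature - material$ref_temperature))
  if (!is.finite(E) || E <= 0)
    stop("temperature outside the validity range of the linear modulus model",
         call. = FALSE)
  E
}

#' @rdname modulus_at_temperature
#' @export
modulus_at_humidity <- function(material, humidity) {
  stopifnot(inherits(material, "material_properties"),
            is.numeric(humidity), length(humidity) == 1L)
  if (is.null(material$humidity_coefficient) || is.null(material$ref_humidity))
    stop("material has no humidity coefficient / reference humidity",
         call. = FALSE)
  E <- material$young_modulus *
    (1 - material$humidity_coefficient * (humidity - material$ref_humidity))
  if (!is.finite(E) || E <= 0)
    stop("humidity outside the validity range of the linear modulus model",
         call. = FALSE)
  E
}

#' @rdname modulus_at_temperature
#' @export
modulus_at_environment <- function(material, conditions) {
  stopifnot(inherits(material, "material_properties"),
            inherits(conditions, "ambient_conditions"))
  if (is.null(material$temp_coefficient) || is.null(material$ref_temperature) ||
      is.null(material$humidity_coefficient) || is.null(material$ref_humidity))
    stop("material must carry both temperature and humidity coefficient pairs",
         call. = FALSE)
  ft <- 1 - material$temp_coefficient *
    (conditions$temperature - material$ref_temperature)
  fh <- 1 - material$humidity_coefficient *
    (conditions$humidity - material$ref_humidity)
  E <- material$young_modulus * ft * fh
  if (!is.finite(E) || E <= 0)
    stop("conditions outside the validity range of the linear modulus model",
         call. = FALSE)
  E
}

#' Self-weight of the filament
#'
#' w = V * rho * g with V = pi * d^2 / 4 * L. Used as the uniformly
#' distributed load (q = w / L) in the deflection model.
#'
#' @param geometry A [monofilament()] object.
#' @param density Material density in kg m^-3 (>= 0), or a
#'   [material_properties()] object.
#' @return Weight in newtons.
#' @export
self_weight <- function(geometry, density) {
  stopifnot(inherits(geometry, "monofilament"))
  if (inherits(density, "material_properties")) density <- density$density
  stopifnot(is.numeric(density), length(density) == 1L, is.finite(density),
            density >= 0)
  volume <- pi * geometry$diameter^2 / 4 * geometry$length
  volume * density * .standard_gravity
}

#' Self-weight tip deflection of the horizontal filament
#'
#' During the plantar test the filament is held horizontally and droops
#' under its own weight like a cantilever under a uniformly distributed
#' load. The small-deflection closed form is
#' delta = w * L^3 / (8 * E * I)  (equivalently q * L^4 / (8 * E * I) with
#' q = w / L). The result carries the deflection as a fraction of the
#' diameter -- a droop comparable to d changes how the tip meets the skin --
#' and a flag for the small-deflection assumption (delta < L / 10).
#'
#' @param geometry A [monofilament()] object.
#' @param young_modulus Young's modulus in Pa, or a [material_properties()]
#'   object (in which case its density is used unless overridden).
#' @param density Material density in kg m^-3; required when
#'   `young_modulus` is a bare number.
#' @return An object of class `"tip_deflection"`: a list with `deflection`
#'   (m), `deflection_um`, `percent_of_diameter`, and
#'   `small_deflection_ok`.
#'
#' @examples
#' nylon <- material_properties(3.65, density = 1140)
#' tip_deflection(monofilament(0.46, 41), nylon)  # 81.81 um, 17.8% of d
#' @export
tip_deflection <- function(geometry, young_modulus, density = NULL) {
  stopifnot(inherits(geometry, "monofilament"))
  E <- as_modulus_pa(young_modulus)
  if (!is.finite(E) || E <= 0)
    stop("young_modulus must be positive", call. = FALSE)
  if (is.null(density)) {
    if (!inherits(young_modulus, "material_properties"))
      stop("density is required when young_modulus is given as a number",
           call. = FALSE)
    density <- young_modulus$density
  }
  w <- self_weight(geometry, density)
  delta <- w * geometry$length^3 / (8 * E * second_moment_area(geometry))
  structure(list(
    deflection = delta,
    deflection_um = delta * 1e6,
    percent_of_diameter = 100 * delta / geometry$diameter,
    small_deflection_ok = delta < geometry$length / 10
  ), class = "tip_deflection")
}

#' @export
print.tip_deflection <- function(x, ...) {
  cat(sprintf("Tip deflection: %.2f um (%.1f%% of diameter)%s\n",
              x$deflection_um, x$percent_of_diameter,
              if (x$small_deflection_ok) "" else
                " [exceeds small-deflection validity: delta >= L/10]"))
  invisible(x)
}
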