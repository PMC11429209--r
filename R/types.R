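#' Monofilament geometry
#'
#' Describes the nylon filament as a slender circular column: its diameter
#' `d` and free length `L`. Dimensions are accepted in millimetres (the unit
#' monofilament datasheets use) and stored internally in metres.
#'
#' @param diameter Filament diameter (> 0).
#' @param length Filament free length (> 0).
#' @param units Unit of both arguments, `"mm"` (default) or `"m"`.
#'
#' @return An object of class `"monofilament"` with fields `diameter` and
#'   `length` in metres.
#'
#' @examples
#' monofilament(diameter = 0.61, length = 38)
#' @export
monofilament <- function(diameter, length, units = c("mm", "m")) {
  units <- match.arg(units)
  stopifnot(is.numeric(diameter), length(diameter) == 1L,
            is.numeric(length), length(length) == 1L)
  if (!is.finite(diameter) || diameter <= 0)
    stop("diameter must be a positive finite number", call. = FALSE)
  if (!is.finite(length) || length <= 0)
    stop("length must be a positive finite number", call. = FALSE)
  scale <- if (units == "mm") 1e-3 else 1
  structure(list(diameter = diameter * scale, length = length * scale),
            class = "monofilament")
}

#' @export
print.monofilament <- function(x, ...) {
  cat(sprintf("Monofilament: d = %.3f mm, L = %.2f mm\n",
              x$diameter * 1e3, x$length * 1e3))
  invisible(x)
}

#' Material properties of the filament
#'
#' Reference Young's modulus and density of the nylon, optionally with the
#' linear environmental coefficients used to correct the modulus for
#' temperature and relative humidity. The coefficients are
#' manufacturer-supplied and have no defaults: operations that need them
#' fail loudly when they are absent.
#'
#' @param young_modulus Reference Young's modulus E0 (> 0).
#' @param density Material density in kg m^-3. Defaults to 1140, a
#'   representative value for extruded Nylon 6.6.
#' @param temp_coefficient Temperature coefficient alpha in 1/degC, the
#'   fractional modulus loss per degree above `ref_temperature` (optional).
#' @param ref_temperature Reference temperature T0 in degC; required when
#'   `temp_coefficient` is given.
#' @param humidity_coefficient Humidity coefficient beta in 1/%RH (optional).
#' @param ref_humidity Reference relative humidity H0 in %RH; required when
#'   `humidity_coefficient` is given.
#' @param units Unit of `young_modulus`: `"GPa"` (default) or `"Pa"`.
#'
#' @return An object of class `"material_properties"`; the modulus is stored
#'   in pascals.
#'
#' @examples
#' nylon <- material_properties(young_modulus = 3.65, density = 1140)
#' @export
material_properties <- function(young_modulus, density = 1140,
                                temp_coefficient = NULL, ref_temperature = NULL,
                                humidity_coefficient = NULL, ref_humidity = NULL,
                                units = c("GPa", "Pa")) {
  units <- match.arg(units)
  stopifnot(is.numeric(young_modulus), length(young_modulus) == 1L,
            is.numeric(density), length(density) == 1L)
  if (!is.finite(young_modulus) || young_modulus <= 0)
    stop("young_modulus must be positive", call. = FALSE)
  if (!is.finite(density) || density <= 0)
    stop("density must be positive", call. = FALSE)
  if (!is.null(temp_coefficient) && is.null(ref_temperature))
    stop("temp_coefficient requires ref_temperature", call. = FALSE)
  if (!is.null(humidity_coefficient) && is.null(ref_humidity))
    stop("humidity_coefficient requires ref_humidity", call. = FALSE)
  structure(list(
    young_modulus = young_modulus * if (units == "GPa") 1e9 else 1,
    density = density,
    temp_coefficient = temp_coefficient,
    ref_temperature = ref_temperature,
    humidity_coefficient = humidity_coefficient,
    ref_humidity = ref_humidity
  ), class = "material_properties")
}

#' @export
print.material_properties <- function(x, ...) {
  cat(sprintf("Material: E0 = %.3f GPa, density = %.0f kg/m^3\n",
              x$young_modulus / 1e9, x$density))
  if (!is.null(x$temp_coefficient))
    cat(sprintf("  alpha = %g /degC at T0 = %g degC\n",
                x$temp_coefficient, x$ref_temperature))
  if (!is.null(x$humidity_coefficient))
    cat(sprintf("  beta = %g /%%RH at H0 = %g %%RH\n",
                x$humidity_coefficient, x$ref_humidity))
  invisible(x)
}

#' End-support boundary condition
#'
#' Encodes the effective-length factor `k` of Euler column theory. The
#' handle end of the filament is always clamped; the skin-contact end is
#' either pinned without slippage (`"clamped_pinned"`, k = 0.7) or pinned
#' and free to slide when the skin offers too little friction
#' (`"clamped_pinned_sliding"`, k = 2.0). Any other factor can be supplied
#' via `name = "custom"`.
#'
#' @param name One of `"clamped_pinned"`, `"clamped_pinned_sliding"`,
#'   `"custom"`.
#' @param k Effective-length factor; only allowed (and required) for
#'   `"custom"` -- the named presets fix k exactly.
#'
#' @return An object of class `"boundary_condition"` with fields `name`
#'   and `k`.
#'
#' @examples
#' boundary_condition("clamped_pinned")          # k = 0.7
#' boundary_condition("clamped_pinned_sliding")  # k = 2.0
#' boundary_condition("custom", k = 1)
#' @export
boundary_condition <- function(name = c("clamped_pinned",
                                        "clamped_pinned_sliding",
                                        "custom"),
                               k = NULL) {
  name <- match.arg(name)
  presets <- c(clamped_pinned = 0.7, clamped_pinned_sliding = 2.0)
  if (name == "custom") {
    if (is.null(k)) stop("custom boundary condition requires k", call. = FALSE)
  } else {
    if (!is.null(k) && k != presets[[name]])
      stop("named presets fix k; use name = \"custom\" for other factors",
           call. = FALSE)
    k <- presets[[name]]
  }
  stopifnot(is.numeric(k), length(k) == 1L)
  if (!is.finite(k) || k <= 0) stop("k must be positive", call. = FALSE)
  structure(list(name = name, k = k), class = "boundary_condition")
}

#' @export
print.boundary_condition <- function(x, ...) {
  cat(sprintf("Boundary condition: %s (k = %g)\n", x$name, x$k))
  invisible(x)
}

# Coerce a user-supplied bc: object, preset name, or bare numeric k.
as_boundary_condition <- function(bc) {
  if (inherits(bc, "boundary_condition")) return(bc)
  if (is.character(bc) && length(bc) == 1L) return(boundary_condition(bc))
  if (is.numeric(bc) && length(bc) == 1L)
    return(boundary_condition("custom", k = bc))
  stop("cannot interpret boundary condition", call. = FALSE)
}

# Young's modulus in Pa from a material object or a bare numeric (Pa).
as_modulus_pa <- function(young_modulus) {
  if (inherits(young_modulus, "material_properties"))
    return(young_modulus$young_modulus)
  stopifnot(is.numeric(young_modulus), length(young_modulus) == 1L)
  young_modulus
}

#' Ambient test conditions
#'
#' Temperature and relative humidity of the environment in which the
#' filament is used, consumed by [modulus_at_environment()].
#'
#' @param temperature Temperature in degC.
#' @param humidity Relative humidity in %RH, within \[0, 100\].
#'
#' @return An object of class `"ambient_conditions"`.
#' @examples
#' ambient_conditions(temperature = 30, humidity = 70)
#' @export
ambient_conditions <- function(temperature, humidity) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.numeric(humidity), length(humidity) == 1L,
            is.finite(temperature), is.finite(humidity))
  if (humidity < 0 || humidity > 100)
    stop("humidity must lie in [0, 100] %RH", call. = FALSE)
  structure(list(temperature = temperature, humidity = humidity),
            class = "ambient_conditions")
}
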