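#' Critical-force grid over length and diameter
#'
#' Sweeps the Euler critical force over a rectangular (L, d) grid at a
#' fixed Young's modulus, in gram-force. Because Fc scales with d^4 and
#' 1/L^2, the grid makes the impact of manufacturing tolerances on the
#' delivered force immediately visible.
#'
#' @param length_range Length-2 numeric: min and max filament length in mm.
#' @param diameter_range Length-2 numeric: min and max diameter in mm.
#' @param young_modulus Young's modulus in Pa, or a [material_properties()]
#'   object.
#' @param bc Boundary condition (default clamped-pinned, k = 0.7).
#' @param steps Number of grid points per axis (>= 2); a scalar or a
#'   length-2 vector `c(lengths, diameters)`. Sampling is linear.
#'
#' @return An object of class `"parameter_grid"`: list with `lengths_mm`,
#'   `diameters_mm`, a `values_gf` matrix (rows indexed by diameter,
#'   columns by length), `young_modulus` (Pa) and `k`.
#'
#' @examples
#' g <- critical_force_grid(c(35, 45), c(0.4, 0.8), 2e9, steps = 5)
#' @export
critical_force_grid <- function(length_range, diameter_range, young_modulus,
                                bc = boundary_condition("clamped_pinned"),
                                steps = 25) {
  stopifnot(is.numeric(length_range), length(length_range) == 2L,
            is.numeric(diameter_range), length(diameter_range) == 2L,
            is.numeric(steps), length(steps) %in% c(1L, 2L))
  if (length(steps) == 1L) steps <- c(steps, steps)
  steps <- as.integer(steps)
  if (any(steps < 2L)) stop("steps must be >= 2", call. = FALSE)
  if (length_range[1] >= length_range[2] || any(length_range <= 0))
    stop("length_range must be positive and strictly increasing", call. = FALSE)
  if (diameter_range[1] >= diameter_range[2] || any(diameter_range <= 0))
    stop("diameter_range must be positive and strictly increasing", call. = FALSE)
  E <- as_modulus_pa(young_modulus)
  bc <- as_boundary_condition(bc)
  lengths <- seq(length_range[1], length_range[2], length.out = steps[1])
  diameters <- seq(diameter_range[1], diameter_range[2], length.out = steps[2])
  values <- outer(diameters, lengths, function(d, l) {
    # closed form, vectorised; identical to per-cell critical_buckling_force
    newton_to_gramforce(
      pi^2 * E * (pi * (d * 1e-3)^4 / 64) / (bc$k * l * 1e-3)^2)
  })
  dimnames(values) <- list(d_mm = sprintf("%.4g", diameters),
                           L_mm = sprintf("%.4g", lengths))
  structure(list(lengths_mm = lengths, diameters_mm = diameters,
                 values_gf = values, young_modulus = E, k = bc$k),
            class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, digits = 2, ...) {
  cat(sprintf("Critical-force grid (gf), E = %.3g GPa, k = %g\n",
              x$young_modulus / 1e9, x$k))
  print(round(x$values_gf, digits))
  invisible(x)
}

#' @export
as.data.frame.parameter_grid <- function(x, ...) {
  data.frame(
    diameter_mm = rep(x$diameters_mm, times = length(x$lengths_mm)),
    length_mm = rep(x$lengths_mm, each = length(x$diameters_mm)),
    critical_force_gf = as.vector(x$values_gf)
  )
}

#' Manufacturing-tolerance deflection table
#'
#' Evaluates the self-weight tip deflection over a 3 x 3 factorial of
#' signed fractional variations on diameter and length (default +/-10%).
#' Each cell reports the absolute deflection in micrometres, the change
#' relative to the unvaried reference cell, and the deflection as a
#' percentage of that cell's own (varied) diameter. The relative change is
#' density- and modulus-independent: it equals
#' (1 + dL)^4 / (1 + dd)^2 - 1 exactly.
#'
#' @param geometry Reference [monofilament()] geometry.
#' @param material A [material_properties()] object (modulus + density).
#' @param variation Fractional variation, strictly between 0 and 1
#'   (default 0.10).
#'
#' @return A data frame of class `"tolerance_table"` with columns
#'   `delta_d`, `delta_L` (signed fractions), `deflection_um`,
#'   `delta_percent` (vs reference cell) and `percent_of_diameter`.
#'   The reference deflection (m) is attached as attribute
#'   `"reference_deflection"`.
#'
#' @examples
#' deflection_tolerance_table(monofilament(0.46, 41),
#'                            material_properties(3.65, density = 1140))
#' @export
deflection_tolerance_table <- function(geometry, material, variation = 0.10) {
  stopifnot(inherits(geometry, "monofilament"),
            inherits(material, "material_properties"),
            is.numeric(variation), length(variation) == 1L)
  if (!is.finite(variation) || variation <= 0 || variation >= 1)
    stop("variation must lie strictly between 0 and 1", call. = FALSE)
  vars <- c(-variation, 0, variation)
  ref <- tip_deflection(geometry, material)$deflection
  cells <- expand.grid(delta_L = vars, delta_d = vars,
                       KEEP.OUT.ATTRS = FALSE)[, c("delta_d", "delta_L")]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    g <- monofilament(geometry$diameter * (1 + cells$delta_d[i]),
                      geometry$length * (1 + cells$delta_L[i]), units = "m")
    td <- tip_deflection(g, material)
    c(deflection_um = td$deflection_um,
      delta_percent = 100 * (td$deflection / ref - 1),
      percent_of_diameter = td$percent_of_diameter)
  })
  out <- cbind(cells, do.call(rbind, res))
  attr(out, "reference_deflection") <- ref
  class(out) <- c("tolerance_table", "data.frame")
  out
}

#' @export
print.tolerance_table <- function(x, ...) {
  # print at instrument-table precision: um to 2 decimals, percents integer
  shown <- data.frame(
    delta_d = sprintf("%+.0f%%", 100 * x$delta_d),
    delta_L = sprintf("%+.0f%%", 100 * x$delta_L),
    deflection_um = sprintf("%.2f", x$deflection_um),
    delta_percent = sprintf("%+.0f%%", x$delta_percent),
    percent_of_diameter = sprintf("%.1f%%", x$percent_of_diameter)
  )
  cat("Self-weight deflection under geometric tolerances\n")
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Boundary-condition comparison across devices
#'
#' For each device measured under clamped-pinned conditions (k = 0.7, the
#' bench calibration setup), estimates the Young's modulus from its
#' geometry and measured critical force, then recomputes the critical
#' force under clamped-sliding conditions (k = 2.0) -- the regime reached
#' when the skin contact point slips. Since Fc scales with 1/k^2, the
#' sliding force is always (0.7/2)^2 = 0.1225 of the pinned force.
#'
#' @param devices A data frame with columns `diameter_mm`, `length_mm`,
#'   `critical_force_gf` (measured at k = 0.7); one row per device.
#'
#' @return A data frame of class `"bc_comparison"` with the inputs plus
#'   `second_moment_m4`, `young_modulus_gpa`, `fc_clamped_pinned_gf`,
#'   `fc_clamped_sliding_gf`. The mean modulus (GPa) across devices is
#'   attached as attribute `"mean_young_modulus_gpa"`.
#'
#' @examples
#' devices <- data.frame(diameter_mm = c(0.61, 0.46),
#'                       length_mm = c(38, 41),
#'                       critical_force_gf = c(28.91, 9.80))
#' boundary_condition_comparison(devices)
#' @export
boundary_condition_comparison <- function(devices) {
  stopifnot(is.data.frame(devices))
  need <- c("diameter_mm", "length_mm", "critical_force_gf")
  if (!all(need %in% names(devices)))
    stop("devices must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(devices) == 0L) stop("devices is empty", call. = FALSE)
  pinned <- boundary_condition("clamped_pinned")
  sliding <- boundary_condition("clamped_pinned_sliding")
  rows <- lapply(seq_len(nrow(devices)), function(i) {
    g <- monofilament(devices$diameter_mm[i], devices$length_mm[i])
    E <- estimate_young_modulus(g, devices$critical_force_gf[i],
                                bc = pinned, units = "gf")
    c(second_moment_m4 = second_moment_area(g),
      young_modulus_gpa = E / 1e9,
      fc_clamped_pinned_gf = newton_to_gramforce(
        critical_buckling_force(g, E, pinned)),
      fc_clamped_sliding_gf = newton_to_gramforce(
        critical_buckling_force(g, E, sliding)))
  })
  out <- cbind(devices[need], do.call(rbind, rows))
  attr(out, "mean_young_modulus_gpa") <- mean(out$young_modulus_gpa)
  class(out) <- c("bc_comparison", "data.frame")
  out
}

#' @export
print.bc_comparison <- function(x, ...) {
  df <- as.data.frame(x)
  df$second_moment_m4 <- sprintf("%.4g", df$second_moment_m4)
  df$young_modulus_gpa <- round(df$young_modulus_gpa, 2)
  df$fc_clamped_pinned_gf <- round(df$fc_clamped_pinned_gf, 2)
  df$fc_clamped_sliding_gf <- round(df$fc_clamped_sliding_gf, 2)
  print(df, row.names = FALSE)
  cat(sprintf("Mean Young's modulus: %.2f GPa\n",
              attr(x, "mean_young_modulus_gpa")))
  invisible(x)
}
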