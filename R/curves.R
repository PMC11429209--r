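#' Force-displacement compression curve
#'
#' One compression cycle recorded by the bench: the filament is advanced
#' towards the force platform and the applied force is sampled along the
#' displacement axis. Displacement is in mm (non-decreasing), force in gf
#' (non-negative).
#'
#' @param displacement Numeric vector of displacements in mm, non-decreasing
#'   with positive span.
#' @param force Numeric vector of forces in gf, same length, all >= 0.
#' @param speed Progression speed in mm s^-1 (optional metadata).
#' @param device_id Device label (optional metadata).
#' @param cycle Compression-cycle index (>= 1).
#'
#' @return An object of class `"fd_curve"`.
#' @export
force_displacement_curve <- function(displacement, force, speed = NA_real_,
                                     device_id = NA_character_, cycle = 1L) {
  stopifnot(is.numeric(displacement), is.numeric(force))
  if (length(displacement) != length(force))
    stop("displacement and force must have the same length", call. = FALSE)
  if (length(displacement) < 2L)
    stop("a curve needs at least two samples", call. = FALSE)
  if (any(!is.finite(displacement)) || any(!is.finite(force)))
    stop("displacement and force must be finite", call. = FALSE)
  if (any(diff(displacement) < 0))
    stop("displacement must be non-decreasing", call. = FALSE)
  if (max(displacement) - min(displacement) <= 0)
    stop("displacement span must be positive", call. = FALSE)
  if (any(force < 0)) stop("forces must be non-negative", call. = FALSE)
  cycle <- as.integer(cycle)
  if (is.na(cycle) || cycle < 1L) stop("cycle must be >= 1", call. = FALSE)
  structure(list(displacement = as.numeric(displacement),
                 force = as.numeric(force),
                 speed = as.numeric(speed), device_id = device_id,
                 cycle = cycle),
            class = "fd_curve")
}

#' @export
print.fd_curve <- function(x, ...) {
  cat(sprintf("Force-displacement curve: %d samples over %.2f mm%s%s\n",
              length(x$force),
              max(x$displacement) - min(x$displacement),
              if (is.na(x$speed)) "" else sprintf(", %g mm/s", x$speed),
              if (is.na(x$device_id)) "" else
                sprintf(" [%s, cycle %d]", x$device_id, x$cycle)))
  invisible(x)
}

#' Extract metrological features from a compression curve
#'
#' A compression cycle shows two regimes: a linear ramp up to the critical
#' force, then a buckling regime in which the force either holds a plateau
#' or overshoots and decays towards one. Features:
#' \describe{
#'   \item{critical_force}{Global maximum force over the cycle (gf).}
#'   \item{plateau_force}{Mean force over the final `plateau_fraction` of
#'     the displacement span (gf).}
#'   \item{overshoot_index}{(critical - plateau) / plateau; 0 for a flat
#'     post-buckling plateau.}
#'   \item{initial_stiffness}{Least-squares slope over the first
#'     `max(slope_window, 10%)` of the samples (gf mm^-1).}
#'   \item{breakpoint_displacement}{First displacement at which the
#'     centered-difference local slope falls below
#'     `slope_drop * initial_stiffness` (mm) -- the onset of buckling.}
#' }
#' A curve whose slope never drops (a pure ramp) has no buckling regime:
#' the breakpoint is `NA` and `no_buckling` is set.
#'
#' @param curve An [force_displacement_curve()] object with >= 8 samples.
#' @param plateau_fraction Final fraction of the displacement span averaged
#'   for the plateau force (default 0.2).
#' @param slope_window Minimum number of leading samples for the stiffness
#'   fit (default 5).
#' @param slope_drop Fraction of the initial stiffness below which the
#'   local slope marks the breakpoint (default 0.2).
#'
#' @return An object of class `"curve_features"`.
#'
#' @examples
#' cu <- generate_curve(critical_force = 15, initial_stiffness = 7.5,
#'                      overshoot = 0.25, noise_sd = 0)
#' extract_features(cu)
#' @export
extract_features <- function(curve, plateau_fraction = 0.2, slope_window = 5,
                             slope_drop = 0.2) {
  stopifnot(inherits(curve, "fd_curve"))
  x <- curve$displacement
  f <- curve$force
  n <- length(f)
  if (n < 8L) stop("feature extraction needs at least 8 samples", call. = FALSE)
  stopifnot(plateau_fraction > 0, plateau_fraction < 1, slope_drop > 0)

  critical <- max(f)
  span <- x[n] - x[1]
  plateau <- mean(f[x >= x[n] - plateau_fraction * span])

  k <- max(as.integer(slope_window), ceiling(0.1 * n))
  k <- min(k, n)
  fit <- stats::lm.fit(cbind(1, x[seq_len(k)]), f[seq_len(k)])
  stiffness <- unname(fit$coefficients[2])

  # centered-difference local slope on interior points
  slope <- (f[3:n] - f[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  below <- which(slope < slope_drop * stiffness)
  if (length(below) == 0L || !is.finite(stiffness) || stiffness <= 0) {
    breakpoint <- NA_real_
    no_buckling <- TRUE
  } else {
    breakpoint <- x[below[1] + 1L]  # interior index offset
    no_buckling <- FALSE
  }

  structure(list(
    critical_force = critical,
    plateau_force = plateau,
    overshoot_index = (critical - plateau) / plateau,
    breakpoint_displacement = breakpoint,
    initial_stiffness = stiffness,
    no_buckling = no_buckling
  ), class = "curve_features")
}

#' @export
print.curve_features <- function(x, ...) {
  cat(sprintf(paste0(
    "Curve features: Fc = %.2f gf, plateau = %.2f gf, overshoot = %.3f\n",
    "  initial stiffness = %.2f gf/mm, breakpoint = %s mm%s\n"),
    x$critical_force, x$plateau_force, x$overshoot_index,
    x$initial_stiffness,
    if (is.na(x$breakpoint_displacement)) "NA" else
      sprintf("%.2f", x$breakpoint_displacement),
    if (x$no_buckling) " [no buckling detected]" else ""))
  invisible(x)
}

#' Fatigue series of per-cycle critical forces
#'
#' The critical force extracted from each of `n` consecutive compression
#' cycles (the bench protocol uses 20 cycles, 3 s apart).
#'
#' @param critical_forces Numeric vector of per-cycle critical forces in
#'   gf, cycle 1..n, all > 0, n >= 2.
#' @param speed Progression speed in mm s^-1 (optional metadata).
#' @param inter_cycle_interval Seconds between consecutive compressions
#'   (default 3).
#'
#' @return An object of class `"fatigue_series"`.
#' @export
fatigue_series <- function(critical_forces, speed = NA_real_,
                           inter_cycle_interval = 3) {
  stopifnot(is.numeric(critical_forces))
  if (length(critical_forces) < 2L)
    stop("a fatigue series needs at least 2 cycles", call. = FALSE)
  if (any(!is.finite(critical_forces)) || any(critical_forces <= 0))
    stop("all critical forces must be positive", call. = FALSE)
  structure(list(critical_forces = as.numeric(critical_forces),
                 speed = as.numeric(speed),
                 inter_cycle_interval = inter_cycle_interval),
            class = "fatigue_series")
}

#' Analyse fatigue decay over repeated compressions
#'
#' Repeated compression lowers the critical force from a first-cycle high
#' towards a plateau. This summarises a [fatigue_series()] by its
#' first-cycle force, the mean and SD of the plateau (cycles
#' `plateau_from_cycle` onwards), the percent decay from first cycle to
#' plateau, and whether the series decays monotonically within a noise
#' tolerance.
#'
#' @param series A [fatigue_series()] object with at least
#'   `plateau_from_cycle + 1` cycles.
#' @param plateau_from_cycle First cycle counted as plateau (default 3:
#'   most filaments settle after the second compression).
#' @param monotone_tolerance Allowed cycle-to-cycle increase (gf) still
#'   counted as monotone decay; default 0.1 gf, the instrument display
#'   resolution.
#'
#' @return An object of class `"fatigue_summary"`: `first_cycle_force`,
#'   `plateau_mean`, `plateau_sd` (gf), `decay_percent`, `monotone_decay`.
#'
#' @examples
#' fs <- generate_fatigue(first_cycle_force = 16, plateau_force = 12,
#'                        noise_sd = 0)
#' analyze_fatigue(fs)
#' @export
analyze_fatigue <- function(series, plateau_from_cycle = 3,
                            monotone_tolerance = 0.1) {
  stopifnot(inherits(series, "fatigue_series"))
  f <- series$critical_forces
  n <- length(f)
  plateau_from_cycle <- as.integer(plateau_from_cycle)
  if (n < plateau_from_cycle + 1L)
    stop(sprintf("need at least %d cycles for plateau from cycle %d",
                 plateau_from_cycle + 1L, plateau_from_cycle), call. = FALSE)
  plateau <- f[plateau_from_cycle:n]
  structure(list(
    first_cycle_force = f[1],
    plateau_mean = mean(plateau),
    plateau_sd = stats::sd(plateau),
    decay_percent = 100 * (f[1] - mean(plateau)) / f[1],
    monotone_decay = all(diff(f) <= monotone_tolerance)
  ), class = "fatigue_summary")
}

#' @export
print.fatigue_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Fatigue: first cycle %.2f gf, plateau %.2f +/- %.2f gf, ",
    "decay %.1f%%%s\n"),
    x$first_cycle_force, x$plateau_mean, x$plateau_sd, x$decay_percent,
    if (x$monotone_decay) " (monotone)" else " (non-monotone)"))
  invisible(x)
}

#' Verification verdict against the nominal force
#'
#' Compares a measured force against the device's nominal rating (10 gf
#' for the diabetic-foot filament) and renders a pass/fail verdict within
#' a symmetric tolerance band. The band is a reporting convention of this
#' package (configurable, always echoed in the report); no standards body
#' currently fixes one for monofilaments.
#'
#' @param x The measured quantity: a bare force in gf, a
#'   `"curve_features"` or `"fd_curve"` object, or a `"fatigue_summary"` or
#'   `"fatigue_series"` object (curves/series are analysed first).
#' @param nominal_force Nominal rating in gf (default 10).
#' @param tolerance_band Half-width of the acceptance band in percent of
#'   nominal (default 10). The verdict is boundary-inclusive.
#' @param use Which measured force to judge: `"plateau"` (default; the
#'   sustained buckling force, or the fatigue plateau mean) or
#'   `"first_cycle"` (the cycle peak / first-cycle force).
#'
#' @return An object of class `"verification_report"`: `nominal_force`,
#'   `measured_force`, `use`, `deviation_percent`, `tolerance_band`,
#'   `verdict` (`"pass"` or `"fail"`).
#'
#' @examples
#' verify_monofilament(10.9)            # pass within +/-10%
#' verify_monofilament(19.33)           # fail: +93.3% over nominal
#' @export
verify_monofilament <- function(x, nominal_force = 10, tolerance_band = 10,
                                use = c("plateau", "first_cycle")) {
  use <- match.arg(use)
  stopifnot(is.numeric(nominal_force), length(nominal_force) == 1L,
            is.numeric(tolerance_band), length(tolerance_band) == 1L)
  if (!is.finite(nominal_force) || nominal_force <= 0)
    stop("nominal_force must be positive", call. = FALSE)
  if (!is.finite(tolerance_band) || tolerance_band < 0)
    stop("tolerance_band must be non-negative", call. = FALSE)

  if (inherits(x, "fd_curve")) x <- extract_features(x)
  if (inherits(x, "fatigue_series")) x <- analyze_fatigue(x)
  measured <- if (inherits(x, "curve_features")) {
    if (use == "plateau") x$plateau_force else x$critical_force
  } else if (inherits(x, "fatigue_summary")) {
    if (use == "plateau") x$plateau_mean else x$first_cycle_force
  } else if (is.numeric(x) && length(x) == 1L && is.finite(x)) {
    x
  } else {
    stop("cannot interpret measured input", call. = FALSE)
  }

  deviation <- 100 * (measured - nominal_force) / nominal_force
  structure(list(
    nominal_force = nominal_force,
    measured_force = measured,
    use = use,
    deviation_percent = deviation,
    tolerance_band = tolerance_band,
    verdict = if (abs(deviation) <= tolerance_band) "pass" else "fail"
  ), class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf(
    "Verification: measured %.2f gf vs nominal %g gf -> %+0.1f%% (band +/-%g%%): %s\n",
    x$measured_force, x$nominal_force, x$deviation_percent,
    x$tolerance_band, toupper(x$verdict)))
  invisible(x)
}

#' Round a force to the instrument display resolution
#'
#' The bench display rounds to one decimal place below 100 gf and to the
#' nearest unit from 100 gf to 500 gf, half-away-from-zero. Classification
#' into the two ranges happens after rounding, so 99.96 gf displays as
#' 100 gf. Forces above the 500 gf transducer limit abort with an overload
#' error, mirroring the instrument's safety behaviour.
#'
#' @param force Force in gf (vectorised), within \[0, 500\].
#' @return The displayed force in gf. Idempotent: rounding a rounded value
#'   leaves it unchanged.
#'
#' @examples
#' display_round(c(11.34, 99.96, 345.55))  # 11.3, 100, 346
#' @export
display_round <- function(force) {
  stopifnot(is.numeric(force), all(is.finite(force)))
  if (any(force < 0)) stop("force must be non-negative", call. = FALSE)
  if (any(force > 500))
    stop("overload: force exceeds the 500 gf measurement limit", call. = FALSE)
  half_away <- function(x, res) floor(x / res + 0.5) * res  # x >= 0
  one_dp <- half_away(force, 0.1)
  out <- ifelse(one_dp >= 100, half_away(force, 1), one_dp)
  round(out, 1)  # normalise fp representation of the .1 grid
}
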