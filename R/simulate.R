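# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Simulate a force-displacement compression curve
#'
#' Emulates the two curve morphologies seen on the bench: a linear ramp at
#' `initial_stiffness` up to the critical force, followed either by a flat
#' plateau (`overshoot = 0`) or by an exponential relaxation from the peak
#' towards `plateau_force = critical_force / (1 + overshoot)` with a
#' displacement constant of 10% of the span. Gaussian noise is added
#' pointwise and clipped at zero; samples lie on the regular displacement
#' grid of the bench stepper (0.08 mm default).
#'
#' Given the same spec (including `seed`), the generator returns
#' bit-identical curves.
#'
#' @param critical_force Peak force in gf.
#' @param initial_stiffness Pre-buckling slope in gf mm^-1. Must reach the
#'   peak within the span, else generation fails.
#' @param overshoot Overshoot fraction >= 0; the plateau is
#'   `critical_force / (1 + overshoot)`.
#' @param displacement_span Total displacement in mm (default 10, the
#'   bench protocol).
#' @param sample_step Displacement step in mm (default 0.08, the stepper
#'   resolution). The span must cover at least 8 samples.
#' @param noise_sd SD of additive Gaussian measurement noise in gf
#'   (default 0.03, matching the instrument precision below 100 gf).
#' @param seed Integer seed for reproducibility; `NULL` uses the current
#'   RNG stream.
#' @param speed,device_id,cycle Metadata passed to the curve object.
#' @param round_display Pass the forces through [display_round()] to
#'   emulate the reported instrument resolution.
#'
#' @return An [force_displacement_curve()] object.
#'
#' @examples
#' cu <- generate_curve(15, initial_stiffness = 7.5, overshoot = 0.25,
#'                      noise_sd = 0, seed = 1)
#' extract_features(cu)$overshoot_index  # ~0.25
#' @export
generate_curve <- function(critical_force, initial_stiffness, overshoot = 0,
                           displacement_span = 10, sample_step = 0.08,
                           noise_sd = 0.03, seed = NULL,
                           speed = NA_real_, device_id = "synthetic",
                           cycle = 1L, round_display = FALSE) {
  stopifnot(critical_force > 0, initial_stiffness > 0, overshoot >= 0,
            displacement_span > 0, sample_step > 0, noise_sd >= 0)
  x <- seq(0, displacement_span, by = sample_step)
  if (length(x) < 8L)
    stop("span/step must yield at least 8 samples", call. = FALSE)
  xc <- critical_force / initial_stiffness
  if (xc > displacement_span)
    stop("peak unreachable: initial_stiffness too low for the span",
         call. = FALSE)
  plateau <- critical_force / (1 + overshoot)
  lambda <- 0.1 * displacement_span
  f <- ifelse(x <= xc,
              initial_stiffness * x,
              plateau + (critical_force - plateau) * exp(-(x - xc) / lambda))
  if (noise_sd > 0)
    f <- pmax(0, f + with_seed(seed, stats::rnorm(length(x), 0, noise_sd)))
  if (round_display) f <- display_round(f)
  force_displacement_curve(x, f, speed = speed, device_id = device_id,
                           cycle = cycle)
}

#' Simulate a fatigue series of per-cycle critical forces
#'
#' Emulates the decay of the critical force over repeated compressions:
#' F(n) = plateau + (first - plateau) * exp(-decay_rate * (n - 1)) plus
#' Gaussian noise. Deterministic given the seed.
#'
#' @param first_cycle_force First-cycle critical force in gf.
#' @param plateau_force Asymptotic plateau force in gf; must satisfy
#'   `first_cycle_force >= plateau_force > 0`.
#' @param decay_rate Per-cycle exponential decay rate (> 0; default 1.5,
#'   reaching the plateau within the first few compressions).
#' @param cycles Number of cycles (default 20, the bench protocol).
#' @param noise_sd SD of additive Gaussian noise in gf (default 0.03).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param speed,inter_cycle_interval Metadata passed to the series object.
#'
#' @return A [fatigue_series()] object.
#'
#' @examples
#' fs <- generate_fatigue(16, 12, noise_sd = 0, seed = 1)
#' analyze_fatigue(fs)$decay_percent
#' @export
generate_fatigue <- function(first_cycle_force, plateau_force,
                             decay_rate = 1.5, cycles = 20, noise_sd = 0.03,
                             seed = NULL, speed = NA_real_,
                             inter_cycle_interval = 3) {
  stopifnot(plateau_force > 0, first_cycle_force >= plateau_force,
            decay_rate > 0, cycles >= 2, noise_sd >= 0)
  n <- seq_len(cycles)
  f <- plateau_force +
    (first_cycle_force - plateau_force) * exp(-decay_rate * (n - 1))
  if (noise_sd > 0)
    f <- pmax(.Machine$double.eps,
              f + with_seed(seed, stats::rnorm(cycles, 0, noise_sd)))
  fatigue_series(f, speed = speed,
                 inter_cycle_interval = inter_cycle_interval)
}

#' Simulate paired reference/candidate measurements
#'
#' Emulates the instrument-validation protocol: true forces are measured
#' by a reference instrument (noise `noise_ref`) and by the candidate
#' instrument with a systematic `bias` and noise `noise_cand`. Optionally
#' a multiplicative jitter uniform on \[1, 1.25\] perturbs the true forces
#' before measurement, emulating the protocol's random increase of up to
#' 25% on each reference point.
#'
#' @param true_forces Numeric vector of true forces in gf.
#' @param bias Systematic candidate offset in gf (default 0).
#' @param noise_ref,noise_cand Gaussian noise SDs in gf (>= 0).
#' @param jitter Apply the multiplicative \[1, 1.25\] jitter (default
#'   FALSE).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#'
#' @return A data frame with columns `reference_gf` and `measured_gf`,
#'   suitable for [bland_altman()] and [write_pairs_csv()].
#'
#' @examples
#' pairs <- generate_pairs(rep(10, 100), bias = 0.3, noise_ref = 0,
#'                         noise_cand = 0.2, seed = 1)
#' bland_altman(pairs)$mean_difference
#' @export
generate_pairs <- function(true_forces, bias = 0, noise_ref = 0,
                           noise_cand = 0, jitter = FALSE, seed = NULL) {
  stopifnot(is.numeric(true_forces), length(true_forces) >= 1L,
            noise_ref >= 0, noise_cand >= 0)
  n <- length(true_forces)
  with_seed(seed, {
    truth <- if (jitter) true_forces * stats::runif(n, 1, 1.25) else true_forces
    data.frame(
      reference_gf = truth + stats::rnorm(n, 0, noise_ref),
      measured_gf = truth + bias + stats::rnorm(n, 0, noise_cand)
    )
  })
}
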