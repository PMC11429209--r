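# Shared fixtures, built in code.

# Four bench-characterised 10 gf devices: geometry, modulus estimated from
# the clamped-pinned (k = 0.7) critical-force measurement, and the printed
# inverse/forward quantities used as oracles in the tests.
table5_devices <- data.frame(
  diameter_mm = c(0.61, 0.46, 0.71, 0.52),
  length_mm = c(38, 41, 38, 38),
  young_modulus_gpa = c(2.99, 3.65, 1.68, 2.65),
  critical_force_gf = c(28.91, 9.80, 29.81, 13.50)
)

# Noise-free curve with the breakpoint on the sampling grid, so the sampled
# maximum equals the nominal peak exactly (15 / 7.5 = 2.0 mm = 25 x 0.08).
flat_curve <- function(...) {
  generate_curve(critical_force = 15, initial_stiffness = 7.5,
                 overshoot = 0, noise_sd = 0, ...)
}

overshoot_curve <- function(...) {
  generate_curve(critical_force = 15, initial_stiffness = 7.5,
                 overshoot = 0.25, noise_sd = 0, ...)
}
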