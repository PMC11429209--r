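test_that("curve constructor enforces its invariants", {
  expect_error(force_displacement_curve(c(0, 1, 0.5), c(1, 2, 3)),
               "non-decreasing")
  expect_error(force_displacement_curve(c(0, 1), c(1, -2)), "non-negative")
  expect_error(force_displacement_curve(c(0, 0, 0), c(1, 2, 3)), "span")
  expect_error(force_displacement_curve(c(0, 1), c(1, 2, 3)), "same length")
})

test_that("features of a flat-plateau curve: peak = plateau, zero overshoot", {
  feats <- extract_features(flat_curve())
  expect_equal(feats$critical_force, 15)
  expect_equal(feats$plateau_force, 15, tolerance = 1e-6)
  expect_equal(feats$overshoot_index, 0, tolerance = 1e-6)
  expect_equal(feats$initial_stiffness, 7.5, tolerance = 1e-6)
  expect_false(feats$no_buckling)
  # breakpoint sits at the ramp/plateau transition (2 mm), within one step
  expect_lt(abs(feats$breakpoint_displacement - 2), 0.2)
})

test_that("features of an overshooting curve recover the generator truth", {
  feats <- extract_features(overshoot_curve())
  expect_equal(feats$critical_force, 15)
  # plateau = 15 / 1.25 = 12, up to the residual exponential tail
  expect_equal(feats$plateau_force, 12, tolerance = 1e-3)
  expect_equal(feats$overshoot_index, 0.25, tolerance = 5e-3)
})

test_that("a pure linear ramp is flagged as no buckling detected", {
  x <- seq(0, 10, by = 0.5)
  ramp <- force_displacement_curve(x, 2 * x)
  feats <- extract_features(ramp)
  expect_true(feats$no_buckling)
  expect_true(is.na(feats$breakpoint_displacement))
  expect_error(
    extract_features(force_displacement_curve(c(0, 1, 2), c(0, 1, 2))),
    "8 samples")
})

test_that("fatigue analysis summarises decay to a plateau", {
  const <- fatigue_series(rep(10, 20))
  s <- analyze_fatigue(const)
  expect_equal(s$decay_percent, 0)
  expect_equal(s$plateau_sd, 0)
  expect_true(s$monotone_decay)

  rising <- fatigue_series(seq(10, 15, length.out = 10))
  expect_false(analyze_fatigue(rising)$monotone_decay)

  # noise-free exponential decay 16 -> 12: decay 25% (fast decay so the
  # plateau window has no residual transient)
  fs <- generate_fatigue(16, 12, decay_rate = 30, noise_sd = 0)
  s2 <- analyze_fatigue(fs)
  expect_equal(s2$first_cycle_force, 16)
  expect_equal(s2$plateau_mean, 12, tolerance = 1e-12)
  expect_equal(s2$decay_percent, 25, tolerance = 1e-12)
  expect_true(s2$monotone_decay)

  expect_error(analyze_fatigue(fatigue_series(c(12, 11, 10)),
                               plateau_from_cycle = 3),
               "at least 4 cycles")
  expect_error(fatigue_series(10), "at least 2")
  expect_error(fatigue_series(c(10, 0)), "positive")
})

test_that("verification verdicts follow the symmetric inclusive band", {
  expect_equal(verify_monofilament(10)$deviation_percent, 0)
  expect_equal(verify_monofilament(10)$verdict, "pass")
  expect_equal(verify_monofilament(10.9)$verdict, "pass")
  expect_equal(verify_monofilament(11)$verdict, "pass")  # boundary inclusive
  r <- verify_monofilament(19.33)
  expect_equal(r$deviation_percent, 93.3, tolerance = 1e-6)
  expect_equal(r$verdict, "fail")
})

test_that("verdicts are monotone in the band and accept curves and series", {
  # widening the band never flips pass -> fail
  for (m in c(8.5, 10, 11.2, 19.33)) {
    verdicts <- vapply(c(2, 5, 10, 25, 100), function(b)
      verify_monofilament(m, tolerance_band = b)$verdict, "")
    expect_true(all(diff(verdicts == "pass") >= 0))
  }
  # a curve is analysed first; plateau vs first_cycle selects the feature
  cu <- overshoot_curve()
  expect_equal(verify_monofilament(cu, use = "first_cycle")$measured_force, 15)
  expect_equal(verify_monofilament(cu, use = "plateau")$measured_force, 12,
               tolerance = 1e-3)
  fs <- generate_fatigue(16, 12, decay_rate = 30, noise_sd = 0)
  expect_equal(verify_monofilament(fs, use = "first_cycle")$measured_force, 16)
  expect_error(verify_monofilament(10, nominal_force = 0), "positive")
})

test_that("display rounding matches the two instrument ranges", {
  expect_equal(display_round(11.34), 11.3)
  expect_equal(display_round(345.55), 346)
  expect_equal(display_round(99.96), 100)  # classified after rounding
  expect_equal(display_round(0), 0)
  expect_error(display_round(501), "overload")
  expect_error(display_round(-1), "non-negative")
})

test_that("display rounding is idempotent and moves values at most half a step", {
  set.seed(99)
  x <- c(runif(200, 0, 99.9), runif(200, 100, 500))
  r <- display_round(x)
  expect_equal(display_round(r), r)
  step <- ifelse(r >= 100, 1, 0.1)
  expect_true(all(abs(r - x) <= step / 2 + 1e-9))
})
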