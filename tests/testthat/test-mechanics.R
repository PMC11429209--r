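test_that("second moment of area follows the circular-section closed form", {
  # printed to 4 s.f. in the device table
  expect_equal(second_moment_area(monofilament(0.61, 38)), 6.797e-15,
               tolerance = 1e-3)
  expect_equal(second_moment_area(monofilament(0.46, 41)), 2.198e-15,
               tolerance = 1e-3)
  # fourth-power scaling: doubling d multiplies I by exactly 16
  g1 <- monofilament(0.35, 40)
  g2 <- monofilament(0.70, 40)
  expect_equal(second_moment_area(g2) / second_moment_area(g1), 16)
  expect_error(monofilament(-0.5, 40), "positive")
  expect_error(monofilament(0.5, 0), "positive")
})

test_that("effective length is k * L with the two named presets", {
  g <- monofilament(0.61, 38)
  expect_equal(effective_length(g, boundary_condition("clamped_pinned")),
               0.02660)
  expect_equal(effective_length(g, boundary_condition("custom", k = 1)),
               g$length)
  expect_equal(effective_length(monofilament(0.46, 41),
                                boundary_condition("clamped_pinned_sliding")),
               0.082)
  expect_equal(boundary_condition("clamped_pinned")$k, 0.7)
  expect_equal(boundary_condition("clamped_pinned_sliding")$k, 2.0)
  expect_error(boundary_condition("clamped_pinned", k = 0.8), "presets fix k")
  expect_error(boundary_condition("custom"), "requires k")
})

test_that("critical buckling force reproduces the worked 19.33 gf example", {
  g <- monofilament(0.61, 38)
  fc <- critical_buckling_force(g, 2e9)
  expect_equal(fc, 0.18961, tolerance = 1e-4)
  expect_equal(newton_to_gramforce(fc), 19.33, tolerance = 1e-3)
  expect_error(critical_buckling_force(g, -1e9), "positive")
})

test_that("critical force warns when the column is not slender", {
  # a stubby 2 mm x 1 mm "column": Le/(d/4) = 0.7*2/0.25 = 5.6 < 30
  stub <- monofilament(1, 2)
  expect_warning(critical_buckling_force(stub, 2e9), "slenderness")
  # typical monofilament geometry is slender: no warning
  expect_silent(critical_buckling_force(monofilament(0.61, 38), 2e9))
})

test_that("force unit conversions are exact inverses", {
  expect_equal(newton_to_gramforce(0.0980665), 10)
  expect_equal(newton_to_gramforce(0), 0)
  forces <- c(0.01, 0.0980665, 0.18961, 4.9)
  expect_equal(gramforce_to_newton(newton_to_gramforce(forces)), forces)
  expect_equal(newton_to_gramforce(gramforce_to_newton(c(10, 19.33))),
               c(10, 19.33))
})

test_that("inverse modulus estimation inverts the buckling formula", {
  g <- monofilament(0.46, 41)
  expect_equal(estimate_young_modulus(g, 9.80, units = "gf") / 1e9, 3.65,
               tolerance = 1e-3)
  expect_equal(
    estimate_young_modulus(monofilament(0.71, 38), 29.81, units = "gf") / 1e9,
    1.68, tolerance = 1e-3)
  expect_error(estimate_young_modulus(g, -1), "positive")
})

test_that("temperature and humidity corrections are linear about reference", {
  m <- material_properties(2, temp_coefficient = 0.005, ref_temperature = 20,
                           humidity_coefficient = 0.004, ref_humidity = 50)
  expect_equal(modulus_at_temperature(m, 20), 2e9)     # identity at T0
  expect_equal(modulus_at_temperature(m, 30), 1.9e9)   # E0 (1 - 0.005*10)
  expect_equal(modulus_at_humidity(m, 50), 2e9)
  expect_equal(modulus_at_humidity(m, 75), 1.8e9)      # E0 (1 - 0.004*25)

  m0 <- material_properties(2, temp_coefficient = 0, ref_temperature = 20)
  expect_equal(modulus_at_temperature(m0, 95), 2e9)    # degenerate coefficient

  plain <- material_properties(2)
  expect_error(modulus_at_temperature(plain, 25), "no temperature")
  expect_error(modulus_at_humidity(plain, 60), "no humidity")
  # far outside the linear model's validity: non-positive modulus
  expect_error(modulus_at_temperature(m, 20 + 1 / 0.005 + 1), "validity")
})

test_that("combined environmental correction composes multiplicatively", {
  m <- material_properties(2, temp_coefficient = 0.005, ref_temperature = 20,
                           humidity_coefficient = 0.004, ref_humidity = 50)
  expect_equal(modulus_at_environment(m, ambient_conditions(20, 50)), 2e9)
  # dT = 10, dH = 25: 2 * 0.95 * 0.9 = 1.71 GPa
  expect_equal(modulus_at_environment(m, ambient_conditions(30, 75)), 1.71e9)
  # zero humidity coefficient reduces to the temperature correction alone
  mt <- material_properties(2, temp_coefficient = 0.005, ref_temperature = 20,
                            humidity_coefficient = 0, ref_humidity = 50)
  expect_equal(modulus_at_environment(mt, ambient_conditions(33, 80)),
               modulus_at_temperature(mt, 33))
  expect_error(modulus_at_environment(material_properties(2),
                                      ambient_conditions(25, 60)),
               "both")
  expect_error(ambient_conditions(20, 120), "0, 100")
})

test_that("material constructor enforces coefficient/reference pairing", {
  expect_error(material_properties(2, temp_coefficient = 0.005),
               "ref_temperature")
  expect_error(material_properties(2, humidity_coefficient = 0.004),
               "ref_humidity")
  expect_error(material_properties(-2), "positive")
  expect_error(material_properties(2, density = 0), "positive")
})

test_that("self-weight and tip deflection match the closed forms", {
  g <- monofilament(0.46, 41)
  # w = (pi d^2/4 L) rho g, hand-evaluated
  expect_equal(self_weight(g, 1140), 7.618e-5, tolerance = 1e-3)
  expect_equal(self_weight(g, 0), 0)
  g2 <- monofilament(0.46, 82)
  expect_equal(self_weight(g2, 1140) / self_weight(g, 1140), 2)

  nylon <- material_properties(3.65, density = 1140)
  td <- tip_deflection(g, nylon)
  expect_equal(td$deflection_um, 81.81, tolerance = 1e-3)
  expect_equal(td$percent_of_diameter, 17.8, tolerance = 1e-2)
  expect_true(td$small_deflection_ok)

  td2 <- tip_deflection(monofilament(0.71, 38),
                        material_properties(1.68, density = 1140))
  expect_equal(td2$deflection_um, 55, tolerance = 2e-3)
  expect_equal(td2$percent_of_diameter, 7.8, tolerance = 1e-2)

  expect_error(tip_deflection(g, 3.65e9), "density")
  expect_equal(tip_deflection(g, 3.65e9, density = 1140)$deflection,
               td$deflection)
})
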