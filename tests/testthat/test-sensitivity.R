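test_that("grid cells agree with direct single-point buckling calls", {
  grid <- critical_force_grid(c(36, 42), c(0.4, 0.8), 2e9, steps = c(4, 5))
  expect_equal(dim(grid$values_gf), c(5L, 4L))
  for (i in seq_along(grid$diameters_mm)) {
    for (j in seq_along(grid$lengths_mm)) {
      g <- monofilament(grid$diameters_mm[i], grid$lengths_mm[j])
      expect_equal(grid$values_gf[i, j],
                   newton_to_gramforce(critical_buckling_force(g, 2e9)))
    }
  }
})

test_that("grid hits the printed single-point values on its nodes", {
  # node (L = 38, d = 0.61) with E = 2 GPa: the 19.33 gf worked example
  grid <- critical_force_grid(c(38, 40), c(0.61, 0.71), 2e9, steps = 3)
  expect_equal(grid$values_gf[1, 1], 19.33, tolerance = 1e-3)
  # node (L = 41, d = 0.46) with E = 3.65 GPa: 9.80 gf
  grid2 <- critical_force_grid(c(40, 41), c(0.45, 0.46), 3.65e9, steps = 2)
  expect_equal(grid2$values_gf[2, 2], 9.80, tolerance = 1e-3)
})

test_that("grid is monotone: increasing in d, decreasing in L", {
  grid <- critical_force_grid(c(30, 50), c(0.3, 0.9), 2.7e9, steps = 8)
  expect_true(all(apply(grid$values_gf, 2, diff) > 0))  # rows: d increases
  expect_true(all(apply(grid$values_gf, 1, diff) < 0))  # cols: L increases
})

test_that("grid rejects degenerate ranges", {
  expect_error(critical_force_grid(c(40, 38), c(0.4, 0.8), 2e9), "increasing")
  expect_error(critical_force_grid(c(38, 40), c(0.8, 0.4), 2e9), "increasing")
  expect_error(critical_force_grid(c(38, 40), c(0.4, 0.8), 2e9, steps = 1),
               ">= 2")
})

test_that("tolerance-table relative cells equal the (1+dL)^4/(1+dd)^2 oracle", {
  tab <- deflection_tolerance_table(monofilament(0.46, 41),
                                    material_properties(3.65, density = 1140))
  oracle <- 100 * ((1 + tab$delta_L)^4 / (1 + tab$delta_d)^2 - 1)
  expect_equal(tab$delta_percent, oracle)
  # centre cell is exactly zero by construction
  centre <- tab$delta_d == 0 & tab$delta_L == 0
  expect_identical(tab$delta_percent[centre], 0)
})

test_that("tolerance-table relative cells are density- and modulus-invariant", {
  g <- monofilament(0.52, 38)
  a <- deflection_tolerance_table(g, material_properties(3.65, density = 1140))
  b <- deflection_tolerance_table(g, material_properties(1.2, density = 950))
  expect_equal(a$delta_percent, b$delta_percent)
})

test_that("tolerance table reproduces the printed +/-10% deflection cells", {
  tab <- deflection_tolerance_table(monofilament(0.46, 41),
                                    material_properties(3.65, density = 1140))
  cell <- function(dd, dl) tab[tab$delta_d == dd & tab$delta_L == dl, ]
  # thinner and longer: the worst case, +81%
  expect_equal(round(cell(-0.1, 0.1)$delta_percent), 81)
  expect_equal(round(cell(0.1, -0.1)$delta_percent), -46)
  expect_equal(cell(0, 0)$deflection_um, 81.81, tolerance = 1e-3)
  expect_equal(cell(0, 0)$percent_of_diameter, 17.8, tolerance = 1e-2)
  expect_error(deflection_tolerance_table(monofilament(0.46, 41),
                                          material_properties(3.65),
                                          variation = 1.2),
               "between 0 and 1")
})

test_that("boundary-condition comparison recovers the printed device table", {
  cmp <- boundary_condition_comparison(table5_devices)
  expect_equal(cmp$young_modulus_gpa, c(2.99, 3.65, 1.68, 2.65),
               tolerance = 2e-3)
  expect_equal(cmp$second_moment_m4[2], 2.198e-15, tolerance = 1e-3)
  # row 1 slides from 28.91 gf to 3.54 gf; row 3 to 3.65 gf
  expect_equal(cmp$fc_clamped_sliding_gf[1], 3.54, tolerance = 2e-3)
  expect_equal(cmp$fc_clamped_sliding_gf[3], 3.65, tolerance = 2e-3)
  expect_equal(attr(cmp, "mean_young_modulus_gpa"), 2.74, tolerance = 1e-3)
  expect_error(boundary_condition_comparison(table5_devices[0, ]), "empty")
})

test_that("boundary-condition comparison round-trips the measured force", {
  cmp <- boundary_condition_comparison(table5_devices)
  expect_equal(cmp$fc_clamped_pinned_gf, table5_devices$critical_force_gf)
  expect_equal(cmp$fc_clamped_sliding_gf / cmp$fc_clamped_pinned_gf,
               rep(0.1225, 4))
})
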