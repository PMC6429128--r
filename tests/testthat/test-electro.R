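test_that("Debye screening follows the monovalent 298 K constant and scaling", {
  expect_equal(debye_length(1.0), 0.304, tolerance = 1e-12)
  expect_equal(debye_length(0.15), 0.304 / sqrt(0.15), tolerance = 1e-12)
  expect_equal(debye_parameter(4 * 0.1), 2 * debye_parameter(0.1),
               tolerance = 1e-12)
  # full-temperature expression stays close to the 298 K constant
  expect_lt(abs(debye_length(1.0, temperature = 297.4) / 0.304 - 1), 0.01)
  expect_error(debye_parameter(-0.1), "positive")
})

test_that("Henry's function interpolates between Hueckel and Smoluchowski limits", {
  expect_equal(henry_function(0), 1)
  expect_equal(henry_function(1e6), 1.5, tolerance = 1e-3)
  expect_equal(henry_function(6), 1.18, tolerance = 0.01)
  ka <- 10^seq(-3, 6, length.out = 1000)
  f <- henry_function(ka)
  expect_true(all(f >= 1 & f <= 1.5))
  expect_true(all(diff(f) >= 0))
  expect_error(henry_function(-1), ">= 0")
})

test_that("zeta from mobility matches Smoluchowski arithmetic and is odd", {
  cond <- electro_conditions()   # 298 K, 0.89 mPa s, eps_r 78.5
  expect_equal(zeta_from_mobility(1.0, cond, f = 1.5), 12.8, tolerance = 0.01)
  expect_equal(zeta_from_mobility(0, cond, 1.2), 0)
  expect_equal(zeta_from_mobility(-0.7, cond, 1.2),
               -zeta_from_mobility(0.7, cond, 1.2), tolerance = 1e-12)
  expect_error(zeta_from_mobility(1, cond, f = 0.8), "f must be")
})

test_that("DHH charge matches hand-checked arithmetic and the joint zeta identity", {
  cond <- electro_conditions()
  z <- dhh_charge(-0.76, 4.7, 6.0 / 4.7, cond, f = 1.18)
  expect_equal(z, -22.2, tolerance = 0.01)
  expect_equal(dhh_charge(0, 4.7, 1, cond), 0)

  # Z from the mobility route equals 4 pi eps a (1 + ka) zeta / e for any
  # parameter set (Henry/DHH joint identity), to 1e-12 relative
  pc <- physical_constants()
  set.seed(42)
  for (i in 1:100) {
    mob <- stats::runif(1, -2, 2)
    a <- stats::runif(1, 1, 12)
    kap <- stats::runif(1, 0.1, 4)
    f <- stats::runif(1, 1, 1.5)
    z1 <- dhh_charge(mob, a, kap, cond, f)
    zeta <- zeta_from_mobility(mob, cond, f) * 1e-3
    eps <- cond$relative_permittivity * pc$vacuum_permittivity
    z2 <- 4 * pi * eps * (a * 1e-9) * (1 + kap * a) * zeta /
      pc$elementary_charge
    expect_lt(abs(z1 - z2) / max(abs(z1), 1e-12), 1e-12)
  }
})

test_that("thermal voltage is linear in T with the published 298 K value", {
  expect_equal(round(thermal_voltage(298), 1), 25.7)
  expect_equal(thermal_voltage(596), 2 * thermal_voltage(298),
               tolerance = 1e-12)
  expect_equal(thermal_voltage(0), 0)
})

test_that("Henderson-Hasselbalch net charge sums term by term", {
  tm <- synth_titration(10, 5, 3.8, 10.5)
  z <- net_charge_at_pH(tm, 7.5)
  # brute-force sum
  zb <- 5 / (1 + 10^(7.5 - 10.5)) - 10 / (1 + 10^(3.8 - 7.5))
  expect_equal(z, zb, tolerance = 1e-12)
  expect_equal(z, -4.99, tolerance = 0.01)
  # single acid at its pKa -> -0.5
  acid <- titration_model(tibble::tibble(label = "a", pKa = 4.2,
                                         charge_sign = -1, count = 1))
  expect_equal(net_charge_at_pH(acid, 4.2), -0.5, tolerance = 1e-12)
  empty_model <- suppressWarnings(synth_titration(0, 0))
  expect_warning(z0 <- net_charge_at_pH(empty_model, c(2, 7, 12)), "empty")
  expect_equal(z0, c(0, 0, 0))
  # strictly decreasing in pH
  ph <- seq(0, 14, by = 0.1)
  expect_true(all(diff(net_charge_at_pH(tm, ph)) < 0))
})

test_that("isoelectric point matches symmetry and a fine-grid zero crossing", {
  expect_equal(isoelectric_point(synth_titration(1, 1, 4, 10)), 7,
               tolerance = 1e-6)
  tm <- synth_titration(10, 5, 3.8, 10.5)
  pI <- isoelectric_point(tm)
  ph <- seq(0, 14, by = 1e-4)
  z <- net_charge_at_pH(tm, ph)
  grid_zero <- ph[which.min(abs(z))]
  expect_lt(abs(pI - grid_zero), 1e-4)
  expect_lt(abs(net_charge_at_pH(tm, pI)), 1e-6)
  expect_error(isoelectric_point(synth_titration(3, 0)), "basic")
})

test_that("the electrokinetics table reproduces the printed charge differences", {
  rec <- tibble::tibble(
    name = c("g-eHER2", "TZM", "complex_1_2", "complex_1_1"),
    mobility = c(-0.76, 0.28, -0.45, -0.29),
    particle_radius = c(4.7, 5.2, 8.4, 6.6),
    z_effective = c(-18.3, 8.3, -26.1, -13.2),
    z_theory = c(-17.0, 10.0, -22.0, -4.0))
  t2 <- suppressWarnings(build_table2(rec))
  expect_equal(round(t2$delta_z, 1), c(1.3, 1.7, 4.1, 9.2))
  # the second published pKa-method column
  rec$z_theory <- c(-16.6, 12.9, -19.9, -3.1)
  t2b <- suppressWarnings(build_table2(rec))
  expect_equal(round(t2b$delta_z[c(1, 2, 4)], 1), c(1.7, 4.6, 10.1))
  # equal charges give zero difference
  rec$z_theory <- rec$z_effective
  expect_equal(suppressWarnings(build_table2(rec))$delta_z, rep(0, 4))
  expect_error(build_table2(tibble::tibble(name = "x", mobility = 1,
                                           particle_radius = NA)),
               "particle_radius")
})

test_that("sequence-derived titration models count residues and termini", {
  tm <- titration_from_sequence("DDKKH")
  g <- tm$groups
  expect_equal(g$count[g$label == "D"], 2L)
  expect_equal(g$count[g$label == "K"], 2L)
  expect_true(all(c("Nterm", "Cterm") %in% g$label))
  tm2 <- titration_from_sequence(c("DK", "DK"))
  expect_equal(tm2$groups$count[tm2$groups$label == "Nterm"], 2L)
})
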