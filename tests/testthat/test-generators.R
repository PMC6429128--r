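test_that("generators are pure functions of spec and seed", {
  expect_identical(pseudo_complex("1:1", 3, 1.2, seed = 9),
                   pseudo_complex("1:1", 3, 1.2, seed = 9))
  c1 <- synth_correlogram(4e-7, seed = 5)
  c2 <- synth_correlogram(4e-7, seed = 5)
  expect_identical(c1$g2, c2$g2)
  expect_false(identical(c1$g2, synth_correlogram(4e-7, seed = 6)$g2))
  # the caller's RNG stream is untouched
  set.seed(1); before <- stats::runif(3)
  set.seed(1); invisible(synth_correlogram(4e-7, seed = 99))
  expect_identical(stats::runif(3), before)
})

test_that("pseudo-complex stoichiometries differ by exactly one receptor lobe", {
  s11 <- pseudo_complex("1:1", 1, seed = 1)
  s12 <- pseudo_complex("1:2", 1, seed = 1)
  lobe_x <- sum(s11$atoms$chain_id == "X")
  expect_equal(nrow(s12$atoms) - nrow(s11$atoms), lobe_x)
  expect_setequal(unique(s12$atoms$chain_id), c("F", "H", "L", "X", "Y"))
  expect_error(pseudo_complex("2:1"), "arg")
  # surrogate molar masses: antibody 149 kDa + 88.7 kDa per receptor
  expect_equal(structure_mass(s11), 149000 + 88700, tolerance = 1e-9)
  expect_equal(structure_mass(s12), 149000 + 2 * 88700, tolerance = 1e-9)
})

test_that("zero jitter with zero hinge spread gives identical models", {
  st <- pseudo_complex("1:1", n_models = 5, jitter_rms = 0, hinge_sd = 0,
                       seed = 2)
  for (k in 2:5) expect_identical(st$models[[k]], st$models[[1]])
})

test_that("measured per-atom displacement RMS tracks the requested jitter", {
  jit <- 1.5
  st <- pseudo_complex("1:1", n_models = 100, jitter_rms = jit, hinge_sd = 0,
                       seed = 4)
  base <- pseudo_complex("1:1", n_models = 1, jitter_rms = 0, hinge_sd = 0,
                         seed = 4)$models[[1]]
  disp2 <- vapply(st$models, function(m) mean(rowSums((m - base)^2)),
                  numeric(1))
  expect_lt(abs(sqrt(mean(disp2)) / jit - 1), 0.10)
})

test_that("synthetic correlograms have the constructed decay and noise level", {
  q <- scattering_vector()
  corr <- synth_correlogram(5e-7, q = q, noise_sigma = 0, seed = 1)
  expect_equal(g1_squared(corr), exp(-2 * (5e-11 * q^2) * corr$lag_times),
               tolerance = 1e-12)
  noisy <- synth_correlogram(5e-7, q = q, n_points = 10000,
                             noise_sigma = 0.004, seed = 2)
  resid <- noisy$g2 - synth_correlogram(5e-7, q = q, n_points = 10000,
                                        noise_sigma = 0, seed = 2)$g2
  expect_lt(abs(stats::sd(resid) / 0.004 - 1), 0.05)
  expect_error(synth_correlogram(-1), "positive")
})

test_that("trajectory schedules place contacts in exactly the rounded frame counts", {
  traj <- synth_trajectory(c(1.0, 0.89), n_frames = 100, seed = 1)
  count_contact <- function(res) sum(vapply(seq_along(traj$models), function(k) {
    m <- traj$models[[k]]
    idx <- which(traj$atoms$residue_id == res)
    sqrt(sum((m[idx[1], ] - m[idx[2], ])^2)) < 5
  }, logical(1)))
  expect_equal(count_contact(1), 100L)
  expect_equal(count_contact(2), 89L)
  expect_error(synth_trajectory(data.frame(residue = c(1, 1),
                                           fraction = c(0.5, 0.7))),
               "conflicting")
  expect_error(synth_trajectory(c(1.5)), "\\[0, 1\\]")
})

test_that("icosphere subdivision counts and vertex radii are exact", {
  m <- icosphere(3, 3)
  expect_equal(nrow(m$triangles), 1280L)
  expect_lt(max(abs(sqrt(rowSums(m$vertices^2)) - 3)), 3e-12)
  expect_error(icosphere(1, 7), "\\[0, 6\\]")
  # inscribed-polyhedron volume deficit at subdivision 4 is 0.217%
  s4 <- mesh_stats(icosphere(1, 4))
  expect_lt(abs(s4$volume - 4 / 3 * pi) / (4 / 3 * pi), 0.003)
})

test_that("ellipsoid meshes carry the analytic volume", {
  v <- mesh_stats(ellipsoid_mesh(3, 1, 1, 5000))$volume
  expect_lt(abs(v - 4 * pi) / (4 * pi), 0.005)
  # degenerate sphere agrees with the icosphere route
  va <- mesh_stats(ellipsoid_mesh(2, 2, 2, 1280))$volume
  vb <- mesh_stats(icosphere(2, 3))$volume
  expect_lt(abs(va - vb) / vb, 0.005)
  # axis order is immaterial
  expect_equal(mesh_stats(ellipsoid_mesh(1, 1, 3, 2000))$volume,
               mesh_stats(ellipsoid_mesh(3, 1, 1, 2000))$volume,
               tolerance = 1e-9)
  expect_error(ellipsoid_mesh(0, 1, 1), "positive")
})
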