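test_that("the SES of a single atom is a sphere of the atomic radius", {
  s <- sphere_set(matrix(0, 1, 3), 2.0)
  m <- triangulate_surface(s, probe_radius = 1.5, grid_spacing = 0.25)
  st <- mesh_stats(m)
  expect_lt(abs(st$area - 4 * pi * 4) / (4 * pi * 4), 0.02)
  expect_equal(st$euler_characteristic, 2L)
  expect_true(validate_mesh(m))
})

test_that("probe 0 reproduces the union-of-spheres volume of two overlapping atoms", {
  s <- sphere_set(rbind(c(0, 0, 0), c(2, 0, 0)), c(2, 2))
  m <- triangulate_surface(s, probe_radius = 0, grid_spacing = 0.15)
  v_exact <- two_sphere_union_volume(2, 2)
  expect_lt(abs(mesh_stats(m)$volume - v_exact) / v_exact, 0.02)
})

test_that("sphere area/volume from the builder converge toward analytic with finer grids", {
  s <- sphere_set(matrix(0, 1, 3), 3.0)
  res <- vapply(c(0.8, 0.4, 0.2), function(h) {
    st <- mesh_stats(triangulate_surface(s, probe_radius = 0, grid_spacing = h))
    c(st$area, st$volume)
  }, numeric(2))
  err_a <- abs(res[1, ] - 4 * pi * 9) / (4 * pi * 9)
  err_v <- abs(res[2, ] - 36 * pi) / (36 * pi)
  expect_true(all(diff(err_a) < 0))
  expect_true(all(diff(err_v) < 0))
})

test_that("disconnected structures yield a warning and two components", {
  s <- sphere_set(rbind(c(0, 0, 0), c(100, 0, 0)), c(2, 2))
  expect_warning(m <- triangulate_surface(s, probe_radius = 0,
                                          grid_spacing = 0.5),
                 "2 connected components")
  expect_length(mesh_components(m), 2L)
  m1 <- suppressWarnings(triangulate_surface(s, probe_radius = 0,
                                             grid_spacing = 0.5,
                                             largest_component = TRUE))
  expect_length(mesh_components(m1), 1L)
})

test_that("coalesce hits the target count, preserves volume and topology", {
  m <- icosphere(1, 5)                       # 20480 triangles
  v0 <- mesh_stats(m)$volume
  d <- coalesce(m, 5000)
  sd_ <- mesh_stats(d)
  expect_lt(abs(sd_$n_triangles - 5000) / 5000, 0.05)
  expect_lt(abs(sd_$volume - v0) / v0, 0.005)
  expect_equal(sd_$euler_characteristic, 2L)
  expect_true(validate_mesh(d))
  # decimated sphere area stays within 1% of analytic
  expect_lt(abs(sd_$area - 4 * pi) / (4 * pi), 0.01)
})

test_that("coalesce is the identity at or above the current count", {
  m <- icosphere(1, 3)
  expect_message(out <- coalesce(m, nrow(m$triangles)), "unchanged")
  expect_identical(out$triangles, m$triangles)
  expect_error(coalesce(m, 50), ">= 100")
})
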