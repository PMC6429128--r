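# Boundary-element solver against closed-form hydrodynamics.  One solve is
# reused for several assertions wherever possible; the triangle counts are
# kept moderate (the acceptance suite runs the full grid).

cond <- solvent_conditions()   # 293 K, 1.002 mPa s

test_that("sphere translational drag obeys Stokes' law pre-extrapolation", {
  mesh <- sphere_mesh(2, 1000)     # ~980 triangles, a = 2 nm
  R6 <- solve_resistance(mesh, cond)
  drag <- mean(diag(R6[1:3, 1:3]))
  expect_lt(abs(drag / (6 * pi * 1.002e-3 * 2e-9) - 1), 0.03)
  # symmetric positive definite
  expect_lt(attr(R6, "asymmetry"), 1e-3)
  w <- hydrocomplex:::grand_scale(R6)
  ev <- eigen(unclass(R6) / outer(w, w), symmetric = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("resistance blocks conjugate under rigid rotation and D is invariant under translation", {
  mesh <- ellipsoid_mesh(2.5, 1, 1, 800)
  R6 <- solve_resistance(mesh, cond)
  D0 <- translational_diffusion(R6, cond)

  Rot <- rotmat(c(1, 2, 0.5), 1.1)
  mr <- mesh
  mr$vertices <- mesh$vertices %*% t(Rot)
  R6r <- solve_resistance(mr, cond)
  # translational block conjugation: R_tt' = Rot R_tt Rot^T
  tt <- unclass(R6)[1:3, 1:3]; ttr <- unclass(R6r)[1:3, 1:3]
  expect_lt(max(abs(ttr - Rot %*% tt %*% t(Rot))) / max(abs(tt)), 1e-3)
  expect_lt(abs(translational_diffusion(R6r, cond) / D0 - 1), 0.005)

  mt <- mesh
  mt$vertices <- sweep(mesh$vertices, 2, c(5, -3, 8), "+")
  expect_lt(abs(translational_diffusion(solve_resistance(mt, cond), cond) /
                  D0 - 1), 0.005)
})

test_that("D halves when lengths double and scales exactly with 1/viscosity", {
  mesh <- sphere_mesh(1.5, 500)
  h1 <- hydro_mesh(mesh, cond, 1e5)
  big <- mesh
  big$vertices <- mesh$vertices * 2
  h2 <- hydro_mesh(big, cond, 1e5)
  expect_lt(abs(h2$D_t / (h1$D_t / 2) - 1), 0.005)
  cond2 <- solvent_conditions(viscosity = 2 * cond$viscosity)
  h3 <- hydro_mesh(mesh, cond2, 1e5)
  expect_equal(h3$D_t, h1$D_t / 2, tolerance = 1e-10)
})

test_that("intrinsic viscosity doubles when volume doubles at fixed molar mass", {
  mesh <- sphere_mesh(2, 500)
  iv1 <- intrinsic_viscosity_bem(mesh, cond, 1e5)
  big <- mesh
  big$vertices <- mesh$vertices * 2^(1 / 3)   # volume x2
  iv2 <- intrinsic_viscosity_bem(big, cond, 1e5)
  expect_lt(abs(as.numeric(iv2) / (2 * as.numeric(iv1)) - 1), 0.005)
})

test_that("ellipsoid diffusion and zero-shear viscosity match the spheroid closed forms", {
  # Scheraga's tabulated zero-shear viscosity factors for spheroids
  nu_ref <- c(`2` = 2.908, `3` = 3.685)
  for (p in c(2, 3)) {
    scan <- hydro_scan(lapply(c(500, 980, 2000),
                              function(n) ellipsoid_mesh(p, 1, 1, n)),
                       cond, 1e5)
    D_ref <- perrin_diffusion(c(p, 1, 1), cond$temperature, cond$viscosity)
    expect_lt(abs(scan$fit_D$intercept / D_ref - 1), 0.02)
    expect_lt(abs(scan$fit_viscosity_factor$intercept / nu_ref[[as.character(p)]] - 1),
              0.03)
    expect_gt(abs(scan$fit_D$correlation_r), 0.9)
  }
})

test_that("the solver's Brownian viscosity decomposition matches the closed-form spheroid term", {
  bs <- hydrocomplex:::bem_solution(ellipsoid_mesh(3, 1, 1, 2000), cond)
  expect_lt(abs(bs$viscosity_factor_brownian / spheroid_brownian_nu(3) - 1),
            0.03)
})

test_that("r_h is algebraically consistent with Stokes-Einstein", {
  h <- hydro_mesh(sphere_mesh(2, 500), cond, 1e5)
  kB <- physical_constants()$boltzmann
  rh <- kB * cond$temperature / (6 * pi * 1.002e-3 * h$D_t * 1e-4) * 1e9
  expect_equal(h$r_h, rh, tolerance = 1e-12)
})

test_that("1/N extrapolation handles exact, constant and degenerate inputs", {
  n <- c(500, 1000, 2000, 4000)
  fit <- extrapolate_inf_triangles(n, 7 + 350 / n)
  expect_equal(fit$intercept, 7, tolerance = 1e-10)
  expect_equal(fit$slope, 350, tolerance = 1e-8)
  expect_equal(abs(fit$correlation_r), 1, tolerance = 1e-12)

  cfit <- extrapolate_inf_triangles(n, rep(4.2, 4))
  expect_equal(cfit$intercept, 4.2, tolerance = 1e-12)
  expect_equal(cfit$slope, 0, tolerance = 1e-12)

  expect_error(extrapolate_inf_triangles(n[1:2], c(1, 2)), "at least 3")
  expect_error(extrapolate_inf_triangles(c(500, 500, 1000), c(1, 2, 3)),
               "distinct")
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "intercept"], 7, tolerance = 1e-10)
  expect_equal(glance(fit)$n_points, 4L)
})

test_that("meshes below the resolution floor and open meshes are rejected", {
  expect_error(solve_resistance(icosphere(1, 1), cond), ">= 100")
  m <- icosphere(1, 3)
  open <- hc_mesh(m$vertices, m$triangles[-1, ], unit = "nm")
  expect_error(solve_resistance(open, cond), "manifold")
})
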