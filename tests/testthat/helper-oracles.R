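# Independent closed-form / brute-force oracles used across the suite.

# Orientation-averaged translational diffusion of a triaxial ellipsoid
# (Oberbeck/Perrin): mobility along axis i is (chi + alpha_i a_i^2)/(16 pi
# eta), D = kT * mean mobility.  Axes in nm; result in cm^2/s.
perrin_diffusion <- function(ax_nm, temperature, viscosity_mPas) {
  ax <- ax_nm
  den <- function(t) sqrt((ax[1]^2 + t) * (ax[2]^2 + t) * (ax[3]^2 + t))
  chi <- stats::integrate(function(t) 1 / den(t), 0, Inf, rel.tol = 1e-12)$value
  al <- vapply(1:3, function(i)
    stats::integrate(function(t) 1 / ((ax[i]^2 + t) * den(t)), 0, Inf,
                     rel.tol = 1e-12)$value, numeric(1))
  mu <- (chi + al * ax^2) / (16 * pi * viscosity_mPas * 1e-3) * 1e9 # 1/(Pa s m)
  1.380649e-23 * temperature * mean(mu) * 1e4
}

# Zero-shear viscosity factor of a spheroid (semi-axes p, 1, 1):
# rigid orientation-averaged part from the exact spheroid stresslet is not
# retabulated here; instead the full zero-shear value is assembled from the
# classical decomposition nu = nu_rigid + B^2 C_perp / (10 eta V), with the
# rigid part taken from Scheraga's tabulation check inside the test.  This
# helper returns only the Brownian part from closed-form spheroid
# hydrodynamics, so the test can cross-check the solver's decomposition.
spheroid_brownian_nu <- function(p) {
  ax <- c(p, 1, 1)
  den <- function(t) sqrt((ax[1]^2 + t) * (ax[2]^2 + t) * (ax[3]^2 + t))
  al <- vapply(1:3, function(i)
    stats::integrate(function(t) 1 / ((ax[i]^2 + t) * den(t)), 0, Inf,
                     rel.tol = 1e-12)$value, numeric(1))
  c_perp_over_eta <- (16 / 3) * pi * (ax[1]^2 + ax[3]^2) /
    (ax[1]^2 * al[1] + ax[3]^2 * al[3])
  B <- (p^2 - 1) / (p^2 + 1)
  V <- 4 / 3 * pi * prod(ax)
  B^2 * c_perp_over_eta / (10 * V)
}

# volume of the union of two equal spheres of radius r at centre distance d
two_sphere_union_volume <- function(r, d) {
  if (d >= 2 * r) return(2 * (4 / 3) * pi * r^3)
  lens <- pi * (4 * r + d) * (2 * r - d)^2 / 12
  2 * (4 / 3) * pi * r^3 - lens
}

# brute-force mass-weighted centre of mass by explicit summation
com_brute <- function(coords, masses) {
  acc <- c(0, 0, 0); tot <- 0
  for (i in seq_len(nrow(coords))) {
    acc <- acc + coords[i, ] * masses[i]
    tot <- tot + masses[i]
  }
  acc / tot
}

# rigid rotation matrix about a unit axis by angle (radians)
rotmat <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# small helper: build a bare sphere-set "structure" for the surface builder
sphere_set <- function(centers, radii) list(centers = centers, radii = radii)
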