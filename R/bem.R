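#' Boundary-element rigid-body hydrodynamics
#'
#' The solver represents the Stokes flow around a rigid triangulated body by
#' a single-layer (Stokeslet) potential with constant force density per
#' triangle, collocated at triangle centroids, with stick (no-slip) boundary
#' conditions.  The self-interaction term is integrated semi-analytically
#' (polar splitting, the 1/r singularity cancels the area Jacobian), which
#' gives the clean O(1/N) discretisation error that the triangle-count
#' extrapolation relies on.
#'
#' @name bem
NULL

# unit-norm orthogonal basis of the 5-dimensional deviatoric strain space
strain_basis <- function() {
  s2 <- 1 / sqrt(2); s6 <- 1 / sqrt(6)
  list(diag(c(s2, -s2, 0)),
       diag(c(s6, s6, -2 * s6)),
       matrix(c(0, s2, 0, s2, 0, 0, 0, 0, 0), 3, 3),
       matrix(c(0, 0, s2, 0, 0, 0, s2, 0, 0), 3, 3),
       matrix(c(0, 0, 0, 0, 0, s2, 0, s2, 0), 3, 3))
}

# volume centroid of a closed mesh (SI coordinates supplied)
mesh_volume_centroid <- function(V, Fc) {
  p1 <- V[Fc[, 1L], , drop = FALSE]
  p2 <- V[Fc[, 2L], , drop = FALSE]
  p3 <- V[Fc[, 3L], , drop = FALSE]
  cr <- cbind(p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2],
              p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3],
              p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  v6 <- rowSums(p1 * cr)
  vol <- sum(v6) / 6
  ctr <- colSums((p1 + p2 + p3) / 4 * v6) / 6 / vol
  list(volume = vol, centroid = ctr)
}

# Full boundary-element solve: 3 translations + 3 rotations + 5 strain
# flows in one factorisation.  Returns the (symmetrised) grand resistance
# matrix about the volume centroid, the force-free orientation-averaged
# viscosity factor, and bookkeeping.
bem_solution <- function(mesh, conditions) {
  validate_mesh(mesh)
  m <- nrow(mesh$triangles)
  if (m < 100L) stop("mesh too coarse for the boundary-element solver (need >= 100 triangles)")
  eta <- eta_si(conditions)
  V <- mesh_vertices_si(mesh)
  Fc <- mesh$triangles
  vc <- mesh_volume_centroid(V, Fc)
  ctr <- (V[Fc[, 1L], ] + V[Fc[, 2L], ] + V[Fc[, 3L], ]) / 3
  x <- sweep(ctr, 2L, vc$centroid)

  Eb <- strain_basis()
  rhs <- matrix(0, 3 * m, 11L)
  for (d in 1:3) rhs[seq(d, 3 * m, 3L), d] <- 1
  ax <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (d in 1:3) {
    w <- ax[[d]]
    u <- cbind(w[2] * x[, 3] - w[3] * x[, 2],
               w[3] * x[, 1] - w[1] * x[, 3],
               w[1] * x[, 2] - w[2] * x[, 1])
    rhs[, 3 + d] <- as.vector(t(u))
  }
  for (k in 1:5) rhs[, 6 + k] <- as.vector(t(x %*% t(Eb[[k]])))

  sol <- .bem_solve_cpp(V, Fc, eta, rhs)
  A <- as.numeric(sol$areas)

  moments <- lapply(seq_len(11L), function(j) {
    f <- t(matrix(sol$density[, j], nrow = 3L))  # m x 3 force densities
    fa <- f * A
    Fm <- colSums(fa)
    Tm <- colSums(cbind(x[, 2] * fa[, 3] - x[, 3] * fa[, 2],
                        x[, 3] * fa[, 1] - x[, 1] * fa[, 3],
                        x[, 1] * fa[, 2] - x[, 2] * fa[, 1]))
    Sm <- crossprod(fa, x)
    Sm <- (Sm + t(Sm)) / 2
    Sm <- Sm - diag(3) * sum(diag(Sm)) / 3
    list(F = Fm, T = Tm, S = Sm)
  })

  R6 <- matrix(0, 6, 6)
  for (j in 1:6) R6[, j] <- c(moments[[j]]$F, moments[[j]]$T)
  asym <- max(abs(R6 - t(R6))) / max(abs(R6))
  R6s <- (R6 + t(R6)) / 2

  # force- and torque-free stresslet for each strain flow
  nu_terms <- vapply(1:5, function(k) {
    mk <- moments[[6 + k]]
    uo <- -solve_grand(R6s, c(mk$F, mk$T))
    S <- mk$S
    for (j in 1:6) S <- S + uo[j] * moments[[j]]$S
    sum(S * Eb[[k]])
  }, numeric(1))
  nu_rigid <- sum(nu_terms) / (5 * 2 * eta * vc$volume)

  # Rotary-Brownian (orientational-entropy) contribution to the zero-shear
  # viscosity: (1/10 eta V) sum_k T_k' Cr^-1 T_k over the strain basis,
  # with T_k the torque on the force-free, non-rotating particle and Cr the
  # force-free rotational resistance (Schur complement).  Exact for bodies
  # of revolution (recovers Simha's spheroid values); zero for a sphere.
  Rtt <- R6s[1:3, 1:3]; Rrt <- R6s[4:6, 1:3]; Rrr <- R6s[4:6, 4:6]
  Cr <- Rrr - Rrt %*% solve(Rtt, t(Rrt))
  brown <- vapply(1:5, function(k) {
    mk <- moments[[6 + k]]
    Tk <- mk$T - Rrt %*% solve(Rtt, mk$F)
    sum(Tk * solve(Cr, Tk))
  }, numeric(1))
  nu_brown <- sum(brown) / (10 * eta * vc$volume)

  list(resistance = R6s, asymmetry = asym,
       viscosity_factor = nu_rigid + nu_brown,
       viscosity_factor_rigid = nu_rigid,
       viscosity_factor_brownian = nu_brown,
       volume = vc$volume, centroid = vc$centroid,
       n_triangles = m, conditions = conditions)
}

#' Grand resistance matrix of a rigid triangulated body
#'
#' Solves the single-layer boundary-integral equation with stick boundary
#' conditions for the 6 rigid-body velocity fields and assembles the 6 x 6
#' grand resistance matrix (SI units: N s/m, N s, N s m blocks) about the
#' body's volume centroid.  The raw matrix is checked for asymmetry
#' (discretisation error, must stay below 1e-3 relative) and then
#' symmetrised.
#'
#' @param mesh a closed outward-oriented [hc_mesh()] with >= 100 triangles.
#' @param conditions a [solvent_conditions()].
#' @return A 6 x 6 symmetric positive definite matrix with attributes
#'   `asymmetry`, `volume` (m^3), `centroid` (m) and `n_triangles`.
#' @export
solve_resistance <- function(mesh, conditions = solvent_conditions()) {
  bs <- bem_solution(mesh, conditions)
  if (bs$asymmetry > 1e-3)
    stop(sprintf("resistance matrix asymmetry %.2g exceeds 1e-3; mesh too irregular",
                 bs$asymmetry))
  w <- grand_scale(bs$resistance)
  ev <- eigen(bs$resistance / outer(w, w), symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("resistance matrix not positive definite (condition estimate %.3g)",
                 max(ev) / abs(min(ev))))
  structure(bs$resistance, asymmetry = bs$asymmetry, volume = bs$volume,
            centroid = bs$centroid, n_triangles = bs$n_triangles)
}

# Solve R6 u = b and invert R6 with the translation/rotation blocks
# rebalanced by the body length scale L = sqrt(tr(R_rr)/tr(R_tt)); the raw
# grand matrix mixes units (eta L, eta L^2, eta L^3) and is numerically
# singular at nanometre scale without this.
grand_scale <- function(R6) {
  L <- sqrt(sum(diag(R6[4:6, 4:6])) / sum(diag(R6[1:3, 1:3])))
  c(1, 1, 1, L, L, L)
}

solve_grand <- function(R6, b) {
  w <- grand_scale(R6)
  x <- solve(R6 / outer(w, w), b / w)
  x / w
}

invert_grand <- function(R6) {
  w <- grand_scale(R6)
  Rs <- R6 / outer(w, w)
  ev <- eigen((Rs + t(Rs)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("resistance matrix must be positive definite")
  solve(Rs) / outer(w, w)
}

# congruence transform of a grand mobility under origin shift by r (SI)
shift_mobility <- function(Mu, r) {
  X <- matrix(c(0, r[3], -r[2], -r[3], 0, r[1], r[2], -r[1], 0), 3, 3)
  P <- rbind(cbind(diag(3), -X), cbind(matrix(0, 3, 3), diag(3)))
  P %*% Mu %*% t(P)
}

# origin shift (from the resistance origin) to the center of diffusion:
# the point where the trace of the translational mobility block is
# minimal.  The objective is exactly quadratic in the shift, so a
# finite-difference Newton step at body-length scale is exact.
center_of_diffusion_shift <- function(Mu) {
  att <- sum(diag(Mu[1:3, 1:3]))
  arr <- sum(diag(Mu[4:6, 4:6]))
  if (arr <= 0) return(c(0, 0, 0))
  s <- sqrt(att / arr)
  f <- function(r) sum(diag(shift_mobility(Mu, r)[1:3, 1:3]))
  g <- numeric(3); H <- matrix(0, 3, 3)
  f0 <- f(c(0, 0, 0))
  e <- diag(3) * s
  fp <- vapply(1:3, function(i) f(e[i, ]), numeric(1))
  fm <- vapply(1:3, function(i) f(-e[i, ]), numeric(1))
  g <- (fp - fm) / (2 * s)
  for (i in 1:3) H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / s^2
  for (i in 1:2) for (j in (i + 1):3) {
    fij <- f(e[i, ] + e[j, ])
    H[i, j] <- H[j, i] <- (fij - fp[i] - fp[j] + f0) / s^2
  }
  if (abs(det(H)) < 1e-300 * max(abs(H))^3) return(c(0, 0, 0))
  -solve(H, g)
}

#' Translational diffusion coefficient from a resistance matrix
#'
#' Inverts the grand resistance into the grand mobility, moves the origin to
#' the center of diffusion (where the trace of the translational mobility
#' block is minimal; the translation-rotation coupling of an arbitrary body
#' otherwise inflates the apparent friction) and returns
#' `D_t = (k_B T / 3) tr(mobility_tt)` in cm^2/s.
#'
#' @param resistance 6 x 6 grand resistance matrix from [solve_resistance()].
#' @param conditions a [solvent_conditions()].
#' @return Translational diffusion coefficient, cm^2/s.
#' @export
translational_diffusion <- function(resistance, conditions = solvent_conditions()) {
  R6 <- unclass(resistance)
  kB <- physical_constants()$boltzmann
  Mu <- invert_grand((R6 + t(R6)) / 2)
  r <- center_of_diffusion_shift(Mu)
  Mu_cd <- shift_mobility(Mu, r)
  D_si <- kB * conditions$temperature * sum(diag(Mu_cd[1:3, 1:3])) / 3
  D_si * 1e4
}

#' Intrinsic viscosity of a rigid triangulated body
#'
#' Computes the orientationally averaged intrinsic viscosity from the
#' force- and torque-free stresslet response to the five independent linear
#' shear (pure strain) flows: `[eta] = nu N_A V / M_w` where `nu` is the
#' dimensionless viscosity factor (2.5 for a sphere, the Einstein value)
#' and `V` the enclosed volume.
#'
#' @param mesh a closed outward-oriented [hc_mesh()].
#' @param conditions a [solvent_conditions()].
#' @param molecular_weight molar mass, g/mol.
#' @return Intrinsic viscosity, cm^3/g, with attribute `viscosity_factor`.
#' @export
intrinsic_viscosity_bem <- function(mesh, conditions = solvent_conditions(),
                                    molecular_weight) {
  if (molecular_weight <= 0) stop("molecular_weight must be positive")
  bs <- bem_solution(mesh, conditions)
  iv <- bs$viscosity_factor * physical_constants()$avogadro *
    (bs$volume * 1e6) / molecular_weight
  structure(iv, viscosity_factor = bs$viscosity_factor)
}

#' Hydrodynamic summary of one mesh
#'
#' One boundary-element factorisation giving translational diffusion,
#' intrinsic viscosity and the Stokes-Einstein hydrodynamic radius.
#'
#' @param mesh a closed outward-oriented [hc_mesh()].
#' @param conditions a [solvent_conditions()].
#' @param molecular_weight molar mass, g/mol.
#' @return A one-row tibble: `n_triangles`, `D_t` (cm^2/s),
#'   `intrinsic_viscosity` (cm^3/g), `r_h` (nm), `viscosity_factor`,
#'   `molecular_weight` (g/mol).
#' @export
hydro_mesh <- function(mesh, conditions = solvent_conditions(),
                       molecular_weight = NA_real_) {
  bs <- bem_solution(mesh, conditions)
  R6 <- bs$resistance
  D <- translational_diffusion(structure(R6), conditions)
  kB <- physical_constants()$boltzmann
  rh_nm <- kB * conditions$temperature /
    (6 * pi * eta_si(conditions) * D * 1e-4) * 1e9
  iv <- if (is.na(molecular_weight)) NA_real_ else
    bs$viscosity_factor * physical_constants()$avogadro *
      (bs$volume * 1e6) / molecular_weight
  tibble::tibble(n_triangles = bs$n_triangles, D_t = D,
                 intrinsic_viscosity = iv, r_h = rh_nm,
                 viscosity_factor = bs$viscosity_factor,
                 molecular_weight = molecular_weight)
}

#' Linear extrapolation to infinite triangle count
#'
#' Boundary-element estimates converge with the number of triangles N with
#' leading error O(1/N); the reported value is the intercept of an ordinary
#' least-squares fit of the quantity against 1/N.
#'
#' @param points data frame with columns `n_triangles` and `value` (>= 3
#'   rows, distinct N), or a numeric vector of N with `values` given
#'   separately.
#' @param values optional numeric vector when `points` is a vector of N.
#' @return An object of class `hc_extrapolation` with `intercept`, `slope`
#'   (per 1/N) and `correlation_r` (Pearson r of value vs 1/N).
#' @export
extrapolate_inf_triangles <- function(points, values = NULL) {
  if (!is.null(values)) points <- data.frame(n_triangles = points, value = values)
  if (!all(c("n_triangles", "value") %in% names(points)))
    stop("points must have columns n_triangles and value")
  if (nrow(points) < 3) stop("need at least 3 (n_triangles, value) points")
  if (anyDuplicated(points$n_triangles))
    stop("n_triangles values must be distinct")
  invn <- 1 / points$n_triangles
  fit <- stats::lm(value ~ invn, data = transform(points, invn = invn))
  r <- if (stats::sd(points$value) == 0) 0 else stats::cor(points$value, invn)
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 correlation_r = r,
                 points = tibble::as_tibble(points)),
            class = "hc_extrapolation")
}

#' @export
print.hc_extrapolation <- function(x, ...) {
  cat(sprintf("<1/N extrapolation> intercept %.6g, slope %.3g, |r| = %.4f (%d points)\n",
              x$intercept, x$slope, abs(x$correlation_r), nrow(x$points)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.hc_extrapolation <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @importFrom generics glance
#' @export
glance.hc_extrapolation <- function(x, ...) {
  tibble::tibble(intercept = x$intercept, slope = x$slope,
                 correlation_r = x$correlation_r, n_points = nrow(x$points))
}

#' Triangle-count scan of one body
#'
#' Runs the solver on a list of meshes of the same body at different
#' triangle counts and extrapolates D and [eta] to infinite N.
#'
#' @param meshes list of [hc_mesh()] objects (same body, different N).
#' @param conditions a [solvent_conditions()].
#' @param molecular_weight molar mass, g/mol.
#' @return A list with `per_n` (tibble of per-mesh results), `fit_D` and
#'   `fit_viscosity` ([extrapolate_inf_triangles()] objects, the latter
#'   `NULL` without molecular weight) and `extrapolated` (one-row tibble).
#' @export
hydro_scan <- function(meshes, conditions = solvent_conditions(),
                       molecular_weight = NA_real_) {
  per_n <- dplyr::bind_rows(lapply(meshes, hydro_mesh, conditions = conditions,
                                   molecular_weight = molecular_weight))
  per_n <- dplyr::arrange(per_n, .data$n_triangles)
  fit_D <- extrapolate_inf_triangles(per_n$n_triangles, per_n$D_t)
  fit_v <- if (all(is.na(per_n$intrinsic_viscosity))) NULL else
    extrapolate_inf_triangles(per_n$n_triangles, per_n$intrinsic_viscosity)
  fit_nu <- extrapolate_inf_triangles(per_n$n_triangles, per_n$viscosity_factor)
  kB <- physical_constants()$boltzmann
  rh_nm <- kB * conditions$temperature /
    (6 * pi * eta_si(conditions) * fit_D$intercept * 1e-4) * 1e9
  list(per_n = per_n, fit_D = fit_D, fit_viscosity = fit_v,
       fit_viscosity_factor = fit_nu,
       extrapolated = tibble::tibble(
         D_t = fit_D$intercept,
         intrinsic_viscosity = if (is.null(fit_v)) NA_real_ else fit_v$intercept,
         viscosity_factor = fit_nu$intercept,
         r_h = rh_nm,
         correlation_r_D = fit_D$correlation_r,
         molecular_weight = molecular_weight))
}
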