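#' Geodesic sphere meshes
#'
#' `icosphere()` subdivides an icosahedron `subdivisions` times (each face
#' into 4), giving `20 * 4^subdivisions` triangles with vertices projected
#' onto the sphere.  `sphere_mesh()` accepts an arbitrary target triangle
#' count and uses the nearest `20 * k^2` geodesic tessellation, which keeps
#' triangle quality uniform at any resolution (no polar thinning).
#'
#' @param radius sphere radius, nm.
#' @param subdivisions integer in `[0, 6]`.
#' @return A [hc_mesh()] in nm, outward-oriented.
#' @export
icosphere <- function(radius, subdivisions = 3) {
  if (subdivisions < 0 || subdivisions > 6 || subdivisions != round(subdivisions))
    stop("subdivisions must be an integer in [0, 6]")
  geodesic_sphere(radius, 2L^as.integer(subdivisions))
}

#' @rdname icosphere
#' @param n_triangles approximate triangle count (>= 20); the realised count
#'   is the nearest `20 * k^2`.
#' @export
sphere_mesh <- function(radius, n_triangles) {
  if (n_triangles < 20) stop("n_triangles must be >= 20")
  k <- max(1L, as.integer(round(sqrt(n_triangles / 20))))
  geodesic_sphere(radius, k)
}

#' Triangulated ellipsoid
#'
#' Geodesic sphere tessellation scaled anisotropically to semi-axes
#' `(a, b, c)`.  Used as the closed-form oracle body (Perrin friction,
#' ellipsoid viscosity) for the hydrodynamic solver.
#'
#' @param a,b,c semi-axes, nm.
#' @param n_triangles approximate triangle count.
#' @return A [hc_mesh()] in nm.
#' @export
ellipsoid_mesh <- function(a, b, c, n_triangles = 2000) {
  if (min(a, b, c) <= 0) stop("semi-axes must be positive")
  mesh <- sphere_mesh(1, n_triangles)
  mesh$vertices <- mesh$vertices %*% diag(c(a, b, c))
  mesh
}

# k-frequency geodesic tessellation of the unit icosahedron, radius scaled.
# Nodes are welded topologically (corner / icosahedral-edge / face-interior
# identity), never by coordinate hashing.
geodesic_sphere <- function(radius, k) {
  if (radius <= 0) stop("radius must be positive")
  phi <- (1 + sqrt(5)) / 2
  base_v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  base_v <- base_v / sqrt(rowSums(base_v^2))
  base_f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))

  n_corner <- 12L
  n_edge_nodes <- if (k > 1) 30L * (k - 1L) else 0L
  n_face_nodes <- if (k > 2) 20L * ((k - 1L) * (k - 2L)) %/% 2L else 0L
  nv <- n_corner + n_edge_nodes + n_face_nodes
  V <- matrix(NA_real_, nv, 3)
  V[1:12, ] <- base_v

  # canonical icosahedral edge list and index lookup
  eall <- rbind(base_f[, c(1, 2)], base_f[, c(2, 3)], base_f[, c(3, 1)])
  ekey <- paste(pmin(eall[, 1], eall[, 2]), pmax(eall[, 1], eall[, 2]))
  edges <- unique(ekey)
  edge_id <- stats::setNames(seq_along(edges), edges)

  # id of the node at barycentric position (b1 on A, b2 on B, b3 on C)
  node_id <- function(va, vb, vc, b1, b2, b3, face, face_base) {
    if (b2 == 0 && b3 == 0) return(va)
    if (b1 == 0 && b3 == 0) return(vb)
    if (b1 == 0 && b2 == 0) return(vc)
    if (b3 == 0) return(edge_node(va, vb, b2))
    if (b1 == 0) return(edge_node(vb, vc, b3))
    if (b2 == 0) return(edge_node(vc, va, b1))
    # face interior: enumerate (b2, b3) with b2 >= 1, b3 >= 1, b2 + b3 <= k - 1
    idx <- ((b2 - 1L) * (2L * (k - 1L) - b2)) %/% 2L + b3
    face_base + idx
  }
  edge_node <- function(vi, vj, t) {
    # t in 1..k-1 measured from vi towards vj
    lo <- min(vi, vj); hi <- max(vi, vj)
    tt <- if (vi == lo) t else k - t
    id <- edge_id[[paste(lo, hi)]]
    n_corner + (id - 1L) * (k - 1L) + tt
  }

  interior_per_face <- if (k > 2) ((k - 1L) * (k - 2L)) %/% 2L else 0L
  tris <- matrix(0L, 20L * k^2, 3L)
  nt <- 0L
  for (face in seq_len(20L)) {
    va <- base_f[face, 1]; vb <- base_f[face, 2]; vc <- base_f[face, 3]
    A <- base_v[va, ]; B <- base_v[vb, ]; C <- base_v[vc, ]
    face_base <- n_corner + n_edge_nodes + (face - 1L) * interior_per_face
    ids <- matrix(0L, k + 1L, k + 1L)
    for (i in 0:k) for (j in 0:(k - i)) {
      b1 <- k - i - j; b2 <- i; b3 <- j
      id <- node_id(va, vb, vc, b1, b2, b3, face, face_base)
      ids[i + 1L, j + 1L] <- id
      if (is.na(V[id, 1])) {
        p <- (A * b1 + B * b2 + C * b3) / k
        V[id, ] <- p / sqrt(sum(p^2))
      }
    }
    for (i in 0:(k - 1L)) for (j in 0:(k - 1L - i)) {
      nt <- nt + 1L
      tris[nt, ] <- c(ids[i + 1L, j + 1L], ids[i + 2L, j + 1L], ids[i + 1L, j + 2L])
      if (j < k - 1L - i) {
        nt <- nt + 1L
        tris[nt, ] <- c(ids[i + 2L, j + 1L], ids[i + 2L, j + 2L], ids[i + 1L, j + 2L])
      }
    }
  }
  mesh <- hc_mesh(V * radius, tris[seq_len(nt), , drop = FALSE], unit = "nm")
  if (mesh_volume_signed(mesh) < 0) mesh <- flip_mesh(mesh)
  mesh
}
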