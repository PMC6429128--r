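#' Rolling-probe molecular surface triangulation
#'
#' Builds a closed triangulated approximation of the solvent-excluded
#' (Connolly) surface of one model of a structure.  The construction is a
#' signed-distance grid over the probe-inflated atomic spheres, isosurface
#' extraction by marching tetrahedra (watertight by construction), then an
#' inward offset of every vertex by the probe radius along the local
#' distance-field gradient.  With `probe_radius = 0` the result is the
#' union-of-spheres (van der Waals) surface, which is the validation case
#' with a closed-form reference.
#'
#' @param structure a [hc_structure()] (or a list with `centers` m x 3 and
#'   `radii` for bare sphere sets), coordinates in A.
#' @param model_index which model to mesh (default 1).
#' @param probe_radius probe sphere radius, A (default 1.5, a water
#'   molecule).
#' @param grid_spacing grid resolution, A (default 0.6).
#' @param largest_component keep only the largest connected component
#'   (default `FALSE`: a disconnected structure yields a warning and a
#'   multi-component mesh).
#' @return A [hc_mesh()] in A.
#' @export
triangulate_surface <- function(structure, model_index = 1L,
                                probe_radius = 1.5, grid_spacing = 0.6,
                                largest_component = FALSE) {
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (grid_spacing <= 0) stop("grid_spacing must be positive")
  if (is_hc_structure(structure)) {
    centers <- structure$models[[model_index]]
    radii <- structure$atoms$radius
  } else {
    centers <- as.matrix(structure$centers)
    radii <- structure$radii
  }
  if (is.null(dim(centers)) || nrow(centers) < 1L) stop("no atoms to mesh")
  rinf <- radii + probe_radius
  margin <- 3 * grid_spacing
  lo <- apply(centers, 2, min) - max(rinf) - 3 * margin
  hi <- apply(centers, 2, max) + max(rinf) + 3 * margin
  dims <- as.integer(ceiling((hi - lo) / grid_spacing)) + 1L
  field <- .sphere_sdf_grid_cpp(centers, rinf, lo, grid_spacing, dims, margin)
  raw <- .march_tets_cpp(field, dims, lo, grid_spacing, 0)
  if (nrow(raw$triangles) == 0L)
    stop("isosurface extraction produced no triangles; decrease grid_spacing")
  mesh <- hc_mesh(raw$vertices, raw$triangles, unit = "A")
  mesh <- drop_degenerate(mesh)
  if (probe_radius > 0) {
    ni <- .nearest_sphere_cpp(mesh$vertices, centers, rinf)
    g <- mesh$vertices - centers[ni, , drop = FALSE]
    g <- g / sqrt(rowSums(g^2))
    mesh$vertices <- mesh$vertices - probe_radius * g
  }
  comps <- mesh_components(mesh)
  if (length(comps) > 1L) {
    if (largest_component) {
      mesh <- comps[[1L]]
    } else {
      warning(sprintf("surface has %d connected components", length(comps)))
    }
  }
  if (mesh_volume_signed(mesh) < 0) mesh <- flip_mesh(mesh)
  mesh
}

# collapse exact-duplicate vertices and drop zero-area triangles produced
# by isosurface clamping
drop_degenerate <- function(mesh) {
  key <- paste(mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  first <- match(key, key)
  remap <- match(first, sort(unique(first)))
  v <- mesh$vertices[sort(unique(first)), , drop = FALSE]
  f <- matrix(remap[mesh$triangles], ncol = 3L)
  ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  hc_mesh(v, f[ok, , drop = FALSE], unit = mesh$unit)
}

#' Coalesce (decimate) a mesh to a target triangle count
#'
#' Quadric edge-collapse decimation with manifold (link-condition) and
#' normal-flip guards, followed by a uniform rescale about the volume
#' centroid that restores the enclosed volume exactly.  The output stays a
#' closed oriented manifold; the realised triangle count is within 5% of
#' the target.
#'
#' @param mesh a closed [hc_mesh()].
#' @param target_triangles desired triangle count (>= 100).
#' @return A [hc_mesh()].
#' @export
coalesce <- function(mesh, target_triangles) {
  if (target_triangles < 100) stop("target_triangles must be >= 100")
  validate_mesh(mesh)
  n <- nrow(mesh$triangles)
  if (target_triangles >= n) {
    message("target at or above current triangle count; mesh returned unchanged")
    return(mesh)
  }
  v0 <- mesh_volume_signed(mesh)
  out <- .decimate_cpp(mesh$vertices, mesh$triangles, as.integer(target_triangles))
  dec <- hc_mesh(out$vertices, out$triangles, unit = mesh$unit)
  validate_mesh_edges(dec)
  if (mesh_volume_signed(dec) < 0) dec <- flip_mesh(dec)
  v1 <- mesh_volume_signed(dec)
  ctr <- colSums(dec$vertices) / nrow(dec$vertices)
  s <- (v0 / v1)^(1 / 3)
  dec$vertices <- sweep(sweep(dec$vertices, 2, ctr) * s, 2, ctr, FUN = "+")
  dec
}
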