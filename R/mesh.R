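#' Triangle mesh objects
#'
#' A `hc_mesh` is a closed, outward-oriented triangulated surface: a list
#' with `vertices` (n x 3 numeric matrix), `triangles` (m x 3 integer
#' matrix of 1-based vertex indices) and a length `unit`, either `"A"`
#' (angstrom) or `"nm"`.  Meshes produced by the surface builder are in the
#' unit of the input structure (angstrom); analytic bodies from the
#' synthetic generators are in nm.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates.
#' @param triangles m x 3 matrix of 1-based vertex indices.
#' @param unit length unit, `"A"` or `"nm"`.
#' @return A `hc_mesh` object.
#' @export
hc_mesh <- function(vertices, triangles, unit = c("A", "nm")) {
  unit <- match.arg(unit)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L || ncol(triangles) != 3L)
    stop("vertices and triangles must have 3 columns")
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles, unit = unit),
            class = "hc_mesh")
}

#' @export
print.hc_mesh <- function(x, ...) {
  s <- mesh_stats(x, check_manifold = FALSE)
  cat(sprintf("<hc_mesh> %d vertices, %d triangles [%s]\n",
              nrow(x$vertices), nrow(x$triangles), x$unit))
  cat(sprintf("  area %.4g %s^2, volume %.4g %s^3, Euler characteristic %d\n",
              s$area, x$unit, s$volume, x$unit, s$euler_characteristic))
  invisible(x)
}

# per-triangle corner coordinate matrices
tri_corners <- function(mesh) {
  list(p1 = mesh$vertices[mesh$triangles[, 1L], , drop = FALSE],
       p2 = mesh$vertices[mesh$triangles[, 2L], , drop = FALSE],
       p3 = mesh$vertices[mesh$triangles[, 3L], , drop = FALSE])
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

mesh_areas <- function(mesh) {
  p <- tri_corners(mesh)
  0.5 * sqrt(rowSums(row_cross(p$p2 - p$p1, p$p3 - p$p1)^2))
}

mesh_volume_signed <- function(mesh) {
  p <- tri_corners(mesh)
  sum(rowSums(p$p1 * row_cross(p$p2, p$p3))) / 6
}

mesh_centroids <- function(mesh) {
  p <- tri_corners(mesh)
  (p$p1 + p$p2 + p$p3) / 3
}

# canonical edge table: one row per undirected edge with its incidence count
mesh_edge_counts <- function(mesh) {
  f <- mesh$triangles
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  table(key)
}

#' Validate that a mesh is a closed oriented 2-manifold
#'
#' Every undirected edge must be used by exactly two triangles with opposite
#' orientation, and the signed enclosed volume must be positive (outward
#' orientation).
#'
#' @param mesh a [hc_mesh()].
#' @param error if `TRUE` (default) a violation is a hard error; otherwise
#'   returns `FALSE` invisibly.
#' @return `TRUE` (invisibly) for a valid mesh.
#' @export
validate_mesh <- function(mesh, error = TRUE) {
  fail <- function(msg) {
    if (error) stop(msg, call. = FALSE)
    return(invisible(FALSE))
  }
  f <- mesh$triangles
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  cnt <- table(key)
  if (any(cnt != 2L)) {
    bad <- names(cnt)[cnt != 2L]
    return(fail(sprintf(
      "mesh is not a closed 2-manifold: %d edge(s) not shared by exactly 2 triangles (e.g. %s)",
      length(bad), paste(utils::head(bad, 3L), collapse = "; "))))
  }
  # consistent orientation: each undirected edge must appear once per direction
  dkey <- paste(e[, 1L], e[, 2L])
  if (anyDuplicated(dkey))
    return(fail("mesh orientation inconsistent: a directed edge occurs twice"))
  if (mesh_volume_signed(mesh) <= 0)
    return(fail("mesh is inward-oriented (signed volume <= 0)"))
  invisible(TRUE)
}

#' Geometric and topological summary of a mesh
#'
#' @param mesh a [hc_mesh()].
#' @param check_manifold validate edge manifoldness first (default `TRUE`);
#'   a non-manifold mesh is then a validation error listing offending edges.
#' @return A list with `area`, `volume` (signed, by the divergence theorem),
#'   `n_triangles`, `n_vertices` and `euler_characteristic`.
#' @export
mesh_stats <- function(mesh, check_manifold = TRUE) {
  if (check_manifold) validate_mesh_edges(mesh)
  f <- mesh$triangles
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  n_edges <- length(unique(paste(pmin(e[, 1L], e[, 2L]),
                                 pmax(e[, 1L], e[, 2L]))))
  n_used <- length(unique(as.vector(f)))
  list(area = sum(mesh_areas(mesh)),
       volume = mesh_volume_signed(mesh),
       n_triangles = nrow(f),
       n_vertices = nrow(mesh$vertices),
       euler_characteristic = n_used - n_edges + nrow(f))
}

# manifold-only check (no orientation/volume requirement)
validate_mesh_edges <- function(mesh) {
  cnt <- mesh_edge_counts(mesh)
  if (any(cnt != 2L)) {
    bad <- names(cnt)[cnt != 2L]
    stop(sprintf("non-manifold mesh: offending edges: %s%s",
                 paste(utils::head(bad, 5L), collapse = "; "),
                 if (length(bad) > 5L) " ..." else ""), call. = FALSE)
  }
  invisible(TRUE)
}

#' Flip mesh orientation
#' @param mesh a [hc_mesh()].
#' @return The mesh with all triangles reversed.
#' @export
flip_mesh <- function(mesh) {
  mesh$triangles <- mesh$triangles[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}

# Orient a combinatorially closed mesh coherently and outward.
orient_mesh <- function(mesh) {
  f <- mesh$triangles
  m <- nrow(f)
  ek <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- ek(edges[, 1L], edges[, 2L])
  owner <- rep(seq_len(m), 3L)
  by_edge <- split(seq_along(key), key)
  adj <- lapply(seq_len(m), function(i) integer(0))
  for (ids in by_edge) {
    tris <- unique(owner[ids])
    if (length(tris) == 2L) {
      adj[[tris[1L]]] <- c(adj[[tris[1L]]], tris[2L])
      adj[[tris[2L]]] <- c(adj[[tris[2L]]], tris[1L])
    }
  }
  seen <- logical(m)
  for (start in seq_len(m)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      i <- queue[[1L]]; queue <- queue[-1L]
      ei <- rbind(f[i, c(1L, 2L)], f[i, c(2L, 3L)], f[i, c(3L, 1L)])
      for (j in adj[[i]]) {
        if (seen[j]) next
        ejd <- rbind(f[j, c(1L, 2L)], f[j, c(2L, 3L)], f[j, c(3L, 1L)])
        same_dir <- any(apply(ei, 1L, function(e)
          any(ejd[, 1L] == e[1L] & ejd[, 2L] == e[2L])))
        if (same_dir) f[j, ] <- f[j, c(1L, 3L, 2L)]
        seen[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  mesh$triangles <- f
  if (mesh_volume_signed(mesh) < 0) mesh <- flip_mesh(mesh)
  mesh
}

#' Split a mesh into connected components
#'
#' @param mesh a [hc_mesh()].
#' @return A list of `hc_mesh` objects ordered by decreasing triangle count.
#' @export
mesh_components <- function(mesh) {
  f <- mesh$triangles
  nv <- nrow(mesh$vertices)
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(f))) {
    a <- find(f[r, 1L]); b <- find(f[r, 2L]); c <- find(f[r, 3L])
    parent[b] <- a; parent[find(c)] <- find(a)
  }
  comp <- vapply(f[, 1L], find, integer(1))
  out <- lapply(split(seq_len(nrow(f)), comp), function(idx) {
    sub <- f[idx, , drop = FALSE]
    used <- sort(unique(as.vector(sub)))
    remap <- match(sub, used)
    hc_mesh(mesh$vertices[used, , drop = FALSE],
            matrix(remap, ncol = 3L), unit = mesh$unit)
  })
  out[order(vapply(out, function(m) nrow(m$triangles), integer(1)),
            decreasing = TRUE)]
}

#' Convert mesh length unit
#' @param mesh a [hc_mesh()].
#' @param unit target unit, `"A"` or `"nm"`.
#' @return The mesh rescaled to `unit`.
#' @export
convert_mesh_unit <- function(mesh, unit = c("A", "nm")) {
  unit <- match.arg(unit)
  if (unit == mesh$unit) return(mesh)
  fac <- if (mesh$unit == "A") 0.1 else 10
  mesh$vertices <- mesh$vertices * fac
  mesh$unit <- unit
  mesh
}

# mesh vertices in metres
mesh_vertices_si <- function(mesh) {
  mesh$vertices * if (mesh$unit == "A") 1e-10 else 1e-9
}
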