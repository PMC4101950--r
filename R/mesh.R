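#' Triangle mesh
#'
#' Surface mesh in millimetres: an `n x 3` vertex matrix and an `m x 3`
#' integer face matrix (1-based vertex indices, consistent counter-clockwise
#' winding seen from outside). Tumor models must be watertight; bone models
#' may be open shells, although the phantoms produced by this package are
#' closed.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of vertex indices.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- if (length(vertices)) as_points_matrix(vertices) else
    matrix(numeric(0), 0, 3)
  dimnames(vertices) <- NULL
  faces <- if (length(faces)) {
    faces <- as.matrix(faces)
    if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix", call. = FALSE)
    storage.mode(faces) <- "integer"
    faces
  } else matrix(integer(0), 0, 3)
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

is_tri_mesh <- function(x) inherits(x, "tri_mesh")

check_mesh <- function(mesh, nonempty = TRUE, what = "mesh") {
  if (!is_tri_mesh(mesh)) stop("expected a 'tri_mesh' object", call. = FALSE)
  if (nonempty && nrow(mesh$vertices) == 0L)
    stop(what, " is empty", call. = FALSE)
  mesh
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Number of vertices / faces
#' @param mesh a [tri_mesh()].
#' @return Integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

# Undirected edge keys "i:j" with i < j, 3 per face.
mesh_edge_keys <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = ":")
}

#' Watertightness check
#'
#' A mesh is treated as watertight (closed and edge-manifold) when every
#' undirected edge is shared by exactly two faces and the two incident faces
#' traverse it in opposite directions (consistent orientation).
#'
#' @param mesh a [tri_mesh()].
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  check_mesh(mesh)
  if (nrow(mesh$faces) == 0L) return(FALSE)
  f <- mesh$faces
  dir_keys <- paste(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1]), sep = ":")
  if (anyDuplicated(dir_keys)) return(FALSE)        # inconsistent winding
  tab <- table(mesh_edge_keys(f))
  all(tab == 2L)
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedron
#' volumes); positive for outward-oriented closed surfaces.
#'
#' @param mesh a [tri_mesh()].
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  check_mesh(mesh)
  if (nrow(mesh$faces) == 0L) return(0)
  V <- mesh$vertices
  a <- V[mesh$faces[, 1], , drop = FALSE]
  b <- V[mesh$faces[, 2], , drop = FALSE]
  cc <- V[mesh$faces[, 3], , drop = FALSE]
  sum(rowSums(a * cross3_rows(b, cc))) / 6
}

#' Vertex centroid and bounding box
#' @param mesh a [tri_mesh()].
#' @return `mesh_centroid()`: 3-vector; `mesh_bbox()`: 2 x 3 matrix
#'   (min row, max row).
#' @export
mesh_centroid <- function(mesh) {
  check_mesh(mesh)
  colMeans(mesh$vertices)
}

#' @rdname mesh_centroid
#' @export
mesh_bbox <- function(mesh) {
  check_mesh(mesh)
  rbind(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
}

#' Minimum signed distance from a mesh to a plane
#'
#' The minimum over all vertices of the signed point-plane distance. Because
#' the signed distance is linear over each triangle, the minimum over the
#' whole surface is attained at a vertex, so this is exact (no surface
#' sampling needed). With the package orientation convention this is the
#' achieved surgical margin SM when `mesh` is the tumor and `plane` the
#' achieved cut plane: positive = clear margin, negative = the plane
#' penetrates the tumor.
#'
#' @param mesh a non-empty [tri_mesh()].
#' @param plane a [plane3()].
#' @return Signed distance (mm).
#' @export
min_signed_distance_to_plane <- function(mesh, plane) {
  check_mesh(mesh)
  min(signed_plane_distance(mesh$vertices, plane))
}

#' Per-vertex normals
#'
#' Area-weighted average of incident face normals, normalized. Vertices on
#' no face get a zero normal.
#'
#' @param mesh a [tri_mesh()].
#' @return n x 3 matrix of unit (or zero) normals.
#' @export
vertex_normals <- function(mesh) {
  check_mesh(mesh)
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  fn <- cross3_rows(b - a, cc - a)   # length = 2 * face area
  acc <- rowsum(rbind(fn, fn, fn), as.integer(F))
  ids <- as.integer(rownames(acc))
  N <- matrix(0, nrow(V), 3)
  N[ids, ] <- acc
  len <- sqrt(rowSums(N^2))
  len[len < 1e-30] <- 1
  N / len
}

# Barycentric vertex areas (one third of each incident face's area);
# sampling vertices with these weights approximates uniform sampling of
# the surface regardless of local triangulation density.
vertex_areas <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  fa <- 0.5 * sqrt(rowSums(cross3_rows(b - a, cc - a)^2))
  acc <- rowsum(rep(fa / 3, 3L), as.integer(F))
  out <- numeric(nrow(V))
  out[as.integer(rownames(acc))] <- acc
  out
}

#' Concatenate meshes
#'
#' Disjoint union of several meshes into one `tri_mesh` (vertex indices are
#' offset; no welding).
#'
#' @param meshes list of [tri_mesh()] objects.
#' @return A [tri_mesh()].
#' @export
merge_meshes <- function(meshes) {
  meshes <- Filter(function(m) nrow(m$vertices) > 0L, meshes)
  if (!length(meshes)) return(tri_mesh(NULL, NULL))
  nv <- vapply(meshes, n_vertices, integer(1))
  off <- cumsum(c(0L, nv[-length(nv)]))
  verts <- do.call(rbind, lapply(meshes, function(m) m$vertices))
  faces <- do.call(rbind, Map(function(m, o) m$faces + o, meshes, off))
  tri_mesh(verts, faces)
}

#' Axis-aligned cube mesh
#'
#' @param center 3-vector (mm).
#' @param size edge length (mm).
#' @return A watertight [tri_mesh()] with 12 triangles.
#' @export
cube_mesh <- function(center = c(0, 0, 0), size = 1) {
  center <- as_point3(center)
  h <- size / 2
  s <- expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h))
  V <- as.matrix(s) + matrix(center, 8, 3, byrow = TRUE)
  # corner order: (---)(+--)(-+-)(++-)(--+)(+-+)(-++)(+++)
  F <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z-  (outward -z)
    c(5, 6, 7), c(6, 8, 7),   # z+
    c(1, 2, 5), c(2, 6, 5),   # y-
    c(3, 7, 4), c(4, 7, 8),   # y+
    c(1, 5, 3), c(3, 5, 7),   # x-
    c(2, 4, 6), c(4, 8, 6))   # x+
  tri_mesh(V, F)
}
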