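#' Oriented infinite plane
#'
#' A cutting plane is stored as an anchor point (mm) and a unit normal. By
#' package convention the normal points toward the tumor/specimen side: the
#' side removed by the cut. With that orientation a positive signed distance
#' means "on the specimen side", so the surgical margin SM of a plane that
#' clears the tumor is positive and a plane that penetrates the tumor gives a
#' negative SM.
#'
#' @param anchor 3-vector, a point on the plane (mm).
#' @param normal 3-vector, plane normal; must be non-zero, normalized to unit
#'   length.
#' @return An object of class `plane3` with fields `anchor` and `normal`.
#' @examples
#' p <- plane3(c(0, 0, -7), c(0, 0, 1))
#' signed_plane_distance(c(0, 0, 0), p)  # 7: origin is on the specimen side
#' @export
plane3 <- function(anchor, normal) {
  anchor <- as_point3(anchor, "anchor")
  normal <- as_point3(normal, "normal")
  n <- vnorm(normal)
  if (n < 1e-12) stop("plane normal is degenerate (zero length)", call. = FALSE)
  structure(list(anchor = anchor, normal = normal / n), class = "plane3")
}

is_plane3 <- function(x) inherits(x, "plane3")

check_plane <- function(plane) {
  if (!is_plane3(plane)) stop("expected a 'plane3' object", call. = FALSE)
  if (abs(vnorm(plane$normal) - 1) > 1e-6)
    stop("plane normal is not unit length", call. = FALSE)
  plane
}

#' @export
print.plane3 <- function(x, ...) {
  cat(sprintf("<plane3> anchor (%.3f, %.3f, %.3f) mm, normal (%.4f, %.4f, %.4f)\n",
              x$anchor[1], x$anchor[2], x$anchor[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Signed distance from points to an oriented plane
#'
#' Computes `dot(point - anchor, normal)` for each point: positive on the
#' side the normal points at (the specimen/tumor side), negative on the
#' remaining-bone side.
#'
#' @param points a 3-vector or an n x 3 matrix of points (mm).
#' @param plane a [plane3()].
#' @return Numeric vector of signed distances (mm).
#' @export
signed_plane_distance <- function(points, plane) {
  check_plane(plane)
  P <- as_points_matrix(points)
  as.numeric((P - matrix(plane$anchor, nrow(P), 3, byrow = TRUE)) %*% plane$normal)
}

#' Translate a plane along its normal
#'
#' @param plane a [plane3()].
#' @param delta signed offset (mm); positive moves the plane toward the
#'   specimen side (its normal direction).
#' @return The translated [plane3()].
#' @export
offset_plane <- function(plane, delta) {
  check_plane(plane)
  plane3(plane$anchor + delta * plane$normal, plane$normal)
}

# Geometric equality of two oriented planes.
planes_equal <- function(a, b, tol = 1e-8) {
  abs(sum(a$normal * b$normal) - 1) < tol &&
    abs(signed_plane_distance(a$anchor, b)) < tol
}

#' Serialize planes to and from JSON-friendly lists
#'
#' Planes are exchanged on disk as `{"anchor":[x,y,z],"normal":[nx,ny,nz]}`
#' in millimetres.
#'
#' @param plane a [plane3()].
#' @param x a list with `anchor` and `normal` fields.
#' @return `plane_to_list()` returns a plain list; `plane_from_list()` a
#'   [plane3()].
#' @export
plane_to_list <- function(plane) {
  check_plane(plane)
  list(anchor = unname(plane$anchor), normal = unname(plane$normal))
}

#' @rdname plane_to_list
#' @export
plane_from_list <- function(x) plane3(unlist(x$anchor), unlist(x$normal))
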