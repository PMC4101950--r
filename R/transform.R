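#' Rigid transform in 3D
#'
#' A proper rigid-body motion `x -> R x + t` with `R` a rotation matrix
#' (orthonormal, det +1) and `t` a translation in millimetres. Used for the
#' post-operative to pre-operative alignment and for simulated scanner
#' displacement.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation 3-vector (mm).
#' @return An object of class `rigid3`.
#' @export
rigid3 <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3x3", call. = FALSE)
  storage.mode(rotation) <- "double"
  translation <- as_point3(translation, "translation")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-7)
    stop("rotation matrix is not orthonormal", call. = FALSE)
  if (abs(det(rotation) - 1) > 1e-7)
    stop("rotation matrix must have det +1 (no reflections)", call. = FALSE)
  structure(list(rotation = rotation, translation = translation), class = "rigid3")
}

is_rigid3 <- function(x) inherits(x, "rigid3")

#' @export
print.rigid3 <- function(x, ...) {
  cat(sprintf("<rigid3> rotation %.2f deg, translation (%.3f, %.3f, %.3f) mm\n",
              rotation_angle_deg(x$rotation),
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Compose and invert rigid transforms
#'
#' `compose_rigid(a, b)` is the transform applying `b` first, then `a`.
#'
#' @param a,b,transform [rigid3()] objects.
#' @return A [rigid3()].
#' @export
compose_rigid <- function(a, b) {
  rigid3(a$rotation %*% b$rotation,
         as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_rigid
#' @export
invert_rigid <- function(transform) {
  Rt <- t(transform$rotation)
  rigid3(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Apply a rigid transform to points or a mesh
#'
#' Pairwise distances are preserved exactly (up to floating point).
#'
#' @param x an n x 3 matrix of points, a 3-vector, or a [tri_mesh()].
#' @param transform a [rigid3()].
#' @return The same kind of object, transformed.
#' @export
apply_rigid <- function(x, transform) {
  if (!is_rigid3(transform)) stop("expected a 'rigid3' transform", call. = FALSE)
  if (inherits(x, "tri_mesh")) {
    x$vertices <- apply_rigid(x$vertices, transform)
    return(x)
  }
  P <- as_points_matrix(x)
  out <- P %*% t(transform$rotation) +
    matrix(transform$translation, nrow(P), 3, byrow = TRUE)
  if (is.matrix(x)) out else as.numeric(out)
}

#' Rotation about an axis
#'
#' Rodrigues rotation matrix for a given axis and angle.
#'
#' @param axis 3-vector, rotation axis (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- unitize(axis, "axis")
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Geodesic angle of a rotation matrix (degrees)
#'
#' @param rotation 3 x 3 rotation matrix.
#' @return Angle in `[0, 180]` degrees.
#' @export
rotation_angle_deg <- function(rotation) {
  ctheta <- (sum(diag(rotation)) - 1) / 2
  acos(min(1, max(-1, ctheta))) * 180 / pi
}

#' Random proper rigid transform
#'
#' Rotation axis uniform on the sphere, rotation angle uniform in
#' `[0, max_angle_deg]`, translation uniform in the cube
#' `[-max_translation, max_translation]^3` (mm). Deterministic given `seed`.
#'
#' @param max_angle_deg maximum rotation angle (degrees).
#' @param max_translation maximum translation per axis (mm).
#' @param seed integer seed.
#' @return A [rigid3()].
#' @export
random_rigid <- function(max_angle_deg = 30, max_translation = 50, seed = 1) {
  with_seed(seed, {
    ax <- stats::rnorm(3)
    ang <- stats::runif(1, 0, max_angle_deg)
    tr <- stats::runif(3, -max_translation, max_translation)
    rigid3(rotation_about_axis(ax, ang), tr)
  })
}

#' Serialize a rigid transform to and from a JSON file
#'
#' Stores the 3 x 3 rotation (row-major), the translation (mm) and any extra
#' fields such as the registration RMS.
#'
#' @param transform a [rigid3()].
#' @param path file path.
#' @param extra named list of extra scalar fields to store alongside.
#' @return `read_rigid_json()` returns a [rigid3()] with extra fields in
#'   `attr(, "meta")`.
#' @export
write_rigid_json <- function(transform, path, extra = list()) {
  obj <- c(list(rotation = unname(lapply(seq_len(3), function(i)
                  unname(transform$rotation[i, ]))),
                translation_mm = unname(transform$translation)), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rigid_json
#' @export
read_rigid_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rot <- matrix(as.numeric(as.matrix(obj$rotation)), 3, 3)
  tr <- rigid3(rot, obj$translation_mm)
  meta <- obj[setdiff(names(obj), c("rotation", "translation_mm"))]
  attr(tr, "meta") <- meta
  tr
}
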