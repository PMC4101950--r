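# Synthetic bone/tumor phantoms. The bone is a thick-walled ellipsoidal
# shell (outer surface minus an inward-scaled copy) with a smooth seeded
# bump that breaks the ellipsoid's symmetry — real pelvic bone is strongly
# asymmetric, and the bump gives the principal-axes pre-alignment a
# well-defined orientation. The accuracy metrics depend only on local cut
# geometry, so a parametric shape with analytic oracles stands in for an
# anatomical pelvis.

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  t,  0), c(1,  t,  0), c(-1, -t,  0), c(1, -t,  0),
    c(0, -1,  t), c(0,  1,  t), c(0, -1, -t), c(0,  1, -t),
    c(t,  0, -1), c(t,  0,  1), c(-t,  0, -1), c(-t,  0,  1))
  V <- V / sqrt(1 + t^2)
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  m <- tri_mesh(V, F)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Unit icosphere mesh
#'
#' Icosahedron subdivided `subdiv` times, vertices projected onto the unit
#' sphere. Deterministic; 20 * 4^subdiv faces.
#'
#' @param subdiv number of subdivision rounds (0-6).
#' @return A watertight [tri_mesh()].
#' @export
icosphere <- function(subdiv = 3) {
  stopifnot(subdiv >= 0, subdiv <= 6)
  m <- icosahedron()
  for (r in seq_len(subdiv)) {
    ref <- subdivide_once(m$vertices, m$faces)
    m <- tri_mesh(ref$vertices / sqrt(rowSums(ref$vertices^2)), ref$faces)
  }
  m
}

#' Ellipsoid mesh
#'
#' @param center 3-vector (mm).
#' @param semi_axes 3-vector of semi-axis lengths (mm).
#' @param subdiv icosphere subdivision level.
#' @return A watertight [tri_mesh()].
#' @export
ellipsoid_mesh <- function(center = c(0, 0, 0), semi_axes = c(1, 1, 1),
                           subdiv = 3) {
  center <- as_point3(center)
  semi_axes <- as_point3(semi_axes, "semi_axes")
  if (any(semi_axes <= 0)) stop("semi-axes must be positive", call. = FALSE)
  s <- icosphere(subdiv)
  V <- s$vertices * matrix(semi_axes, nrow(s$vertices), 3, byrow = TRUE) +
    matrix(center, nrow(s$vertices), 3, byrow = TRUE)
  tri_mesh(V, s$faces)
}

subdiv_for_edge <- function(radius, edge_length) {
  # icosahedron edge on the unit sphere is ~1.0514; each round halves it
  k <- ceiling(log2(1.0514 * radius / edge_length))
  min(5L, max(2L, as.integer(k)))
}

#' Phantom parameters
#'
#' Geometry of the synthetic bone+tumor phantom: a thick-walled ellipsoidal
#' bone shell (centred at the origin) containing an ellipsoidal tumor, with
#' target surface resolution and a seed for the symmetry-breaking bump.
#' Default dimensions are on the scale of a hemipelvis (120 x 80 x 60 mm
#' bone, 24 x 20 x 18 mm tumor, cf. tumor sizes of 60-270 mm in clinical
#' series) at 4 mm mesh resolution.
#'
#' @param bone_semi_axes outer bone semi-axes (mm).
#' @param wall_scale inner (endosteal) surface as a fraction of the outer;
#'   0 gives a solid bone.
#' @param tumor_center tumor centre offset from the bone centre (mm).
#' @param tumor_semi_axes tumor semi-axes (mm).
#' @param edge_length target mesh edge length (mm).
#' @param bump_amplitude outward bump heights (mm), one per prominence.
#'   An ellipsoid is symmetric under half-turns about its axes, which real
#'   pelvic bone is not; the default two well-separated prominences (think
#'   iliac crest and ischial tuberosity) give the shell the landmark
#'   asymmetry that registration relies on clinically.
#' @param bump_width angular widths of the prominences (radians).
#' @param seed integer seed (prominence placement).
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(bone_semi_axes = c(60, 40, 30), wall_scale = 0.55,
                           tumor_center = c(25, 8, 0),
                           tumor_semi_axes = c(12, 10, 9),
                           edge_length = 4, bump_amplitude = c(12, 8),
                           bump_width = c(0.9, 0.7), seed = 1) {
  if (edge_length <= 0) stop("edge_length must be positive", call. = FALSE)
  if (any(as_point3(tumor_semi_axes, "tumor_semi_axes") <= 0))
    stop("tumor semi-axes must be positive", call. = FALSE)
  structure(list(bone_semi_axes = as_point3(bone_semi_axes, "bone_semi_axes"),
                 wall_scale = wall_scale,
                 tumor_center = as_point3(tumor_center, "tumor_center"),
                 tumor_semi_axes = as_point3(tumor_semi_axes, "tumor_semi_axes"),
                 edge_length = edge_length,
                 bump_amplitude = bump_amplitude,
                 bump_width = bump_width,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

#' Generate a bone + tumor phantom
#'
#' Builds the watertight bone shell and tumor meshes described by
#' [phantom_params()]. The tumor must fit strictly inside the outer bone
#' surface (an intraosseous tumor may still protrude into the medullary
#' cavity); violations are an error. Deterministic given the seed.
#'
#' @param params a [phantom_params()].
#' @return List with `bone` and `tumor` ([tri_mesh()] objects) and the
#'   `params` used.
#' @export
make_phantom <- function(params = phantom_params()) {
  if (!inherits(params, "phantom_params"))
    stop("expected 'phantom_params'", call. = FALSE)
  ax <- params$bone_semi_axes
  k_bone <- subdiv_for_edge(max(ax), params$edge_length)
  outer <- ellipsoid_mesh(c(0, 0, 0), ax, k_bone)

  amps <- params$bump_amplitude
  widths <- rep_len(params$bump_width, length(amps))
  if (length(amps) && any(amps > 0)) {
    # well-separated prominence directions (>= 60 degrees apart)
    dirs <- with_seed(params$seed, {
      d <- list(unitize(stats::rnorm(3)))
      while (length(d) < length(amps)) {
        u <- unitize(stats::rnorm(3))
        if (all(vapply(d, function(v) sum(u * v) < 0.5, logical(1))))
          d[[length(d) + 1L]] <- u
      }
      d
    })
    Vu <- outer$vertices / matrix(ax, nrow(outer$vertices), 3, byrow = TRUE)
    Vu <- Vu / sqrt(rowSums(Vu^2))
    r <- sqrt(rowSums(outer$vertices^2))
    grow <- numeric(nrow(outer$vertices))
    for (b in seq_along(amps)) {
      ang <- acos(pmin(1, pmax(-1, Vu %*% dirs[[b]])))
      grow <- grow + amps[b] * exp(-(ang / widths[b])^2)
    }
    outer$vertices <- outer$vertices * as.numeric(1 + grow / r)
  }

  if (params$wall_scale > 0) {
    inner <- ellipsoid_mesh(c(0, 0, 0), ax * params$wall_scale,
                            max(2L, k_bone - 1L))
    inner$faces <- inner$faces[, c(1, 3, 2)]   # orient into the cavity
    bone <- merge_meshes(list(outer, inner))
  } else bone <- outer

  k_tum <- max(3L, subdiv_for_edge(max(params$tumor_semi_axes),
                                   params$edge_length))
  tumor <- ellipsoid_mesh(params$tumor_center, params$tumor_semi_axes, k_tum)

  # containment against the analytic outer ellipsoid (the bump only adds
  # material outward, so the unbumped surface is conservative)
  q <- rowSums((tumor$vertices / matrix(ax, nrow(tumor$vertices), 3,
                                        byrow = TRUE))^2)
  if (any(q >= 1 - 1e-9))
    stop("tumor is not containable inside the bone phantom", call. = FALSE)

  list(bone = bone, tumor = tumor, params = params)
}
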