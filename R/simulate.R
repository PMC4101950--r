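# Simulation of the surgical and imaging chain on a phantom: guided cuts
# with placement noise and saw kerf, then a post-operative scan in an
# arbitrary rigid frame with surface jitter. Every stage is seeded so the
# whole chain is reproducible and carries ground truth.

#' Cut placement noise model
#'
#' A physical guide mispositions the saw slot by a translation along the
#' target normal and a small tilt about an in-plane axis through the cut
#' footprint centroid; the saw blade destroys a kerf of bone on the
#' remaining-bone side. Defaults (1.0 mm translation SD, 1.5 deg tilt SD,
#' 0.9 mm kerf) are a calibration chosen so the simulated accuracy is on the
#' scale reported for guided pelvic resections — they are a plausible error
#' model, not measured ground truth.
#'
#' @param sigma_t SD of the translation along the target normal (mm).
#' @param sigma_theta SD of the tilt (degrees).
#' @param kerf thickness of bone destroyed by the blade (mm, >= 0).
#' @param seed integer seed.
#' @return A list of class `cut_noise`.
#' @export
cut_noise <- function(sigma_t = 1.0, sigma_theta = 1.5, kerf = 0.9, seed = 1) {
  if (sigma_t < 0 || sigma_theta < 0) stop("noise SDs must be >= 0", call. = FALSE)
  if (kerf < 0) stop("kerf must be >= 0", call. = FALSE)
  structure(list(sigma_t = sigma_t, sigma_theta = sigma_theta, kerf = kerf,
                 seed = as.integer(seed)), class = "cut_noise")
}

#' Perturb a target plane by a translation and a tilt
#'
#' The plane is translated `delta` mm along its normal (positive = toward
#' the tumor, i.e. eating into the margin) and tilted `tilt_deg` about an
#' in-plane axis through `centroid` at azimuth `axis_deg` within the plane.
#'
#' @param plane target [plane3()].
#' @param delta translation along the normal (mm).
#' @param tilt_deg tilt angle (degrees).
#' @param axis_deg azimuth of the tilt axis in the plane (degrees).
#' @param centroid 3-vector the tilt axis passes through (normally the cut
#'   footprint centroid).
#' @return The achieved [plane3()].
#' @export
perturb_plane <- function(plane, delta = 0, tilt_deg = 0, axis_deg = 0,
                          centroid = plane$anchor) {
  check_plane(plane)
  p1 <- offset_plane(plane, delta)
  if (tilt_deg == 0) return(p1)
  centroid <- as_point3(centroid)
  E <- plane_basis(plane$normal)
  az <- axis_deg * pi / 180
  axis <- cos(az) * E[, 1] + sin(az) * E[, 2]
  R <- rotation_about_axis(axis, tilt_deg)
  # rotate the plane about the axis through `centroid`
  foot <- centroid - signed_plane_distance(centroid, p1) * p1$normal
  plane3(centroid + as.numeric(R %*% (foot - centroid)),
         as.numeric(R %*% p1$normal))
}

#' Remove the specimen (and kerf) from a bone mesh
#'
#' The removed region is the set of points on the specimen side of every
#' achieved plane, dilated by the kerf: a point is removed when its signed
#' distance `d_j` to each plane exceeds `-kerf`. The returned mesh is the
#' boundary a post-operative scan would see: the kept part of the original
#' bone surface (where some `d_j <= -kerf`) plus one planar cut face per
#' plane, `{d_j = -kerf}` inside the bone restricted to
#' `{d_i >= -kerf}` for the other planes. No interior surface is generated.
#' Where two cut faces meet, their triangulations are independent, so the
#' result is geometrically closed (volumes remain exact) but not
#' necessarily edge-manifold along those seams.
#'
#' @param bone watertight [tri_mesh()].
#' @param planes list of achieved [plane3()] (normals toward the specimen).
#' @param kerf blade kerf (mm, >= 0).
#' @param cap_max_edge radial ring spacing of the cut-face triangulation
#'   (mm); finite so the cut faces carry interior vertices.
#' @return The remaining-bone [tri_mesh()].
#' @export
resect_bone <- function(bone, planes, kerf = 0, cap_max_edge = 3) {
  check_mesh(bone)
  if (kerf < 0) stop("kerf must be >= 0", call. = FALSE)
  cut_planes <- lapply(planes, function(p) offset_plane(check_plane(p), -kerf))
  np <- length(cut_planes)

  # kept original surface, decomposed as {d_j <= 0} * prod_{i<j} {d_i > 0}
  walls <- vector("list", np)
  for (j in seq_len(np)) {
    m <- clip_by_plane(bone, cut_planes[[j]], keep = "negative", cap = FALSE)
    if (j > 1L) for (i in seq_len(j - 1L)) {
      if (nrow(m$vertices) == 0L) break
      m <- clip_by_plane(m, cut_planes[[i]], keep = "positive", cap = FALSE)
    }
    walls[[j]] <- m
  }

  # one planar cut face per plane, trimmed by the other kept half-spaces
  faces <- vector("list", np)
  for (j in seq_len(np)) {
    patch <- section_patch(bone, cut_planes[[j]], cap_max_edge)
    if (is.null(patch)) next
    for (i in seq_len(np)) {
      if (i == j || nrow(patch$vertices) == 0L) next
      patch <- clip_by_plane(patch, cut_planes[[i]], keep = "positive",
                             cap = FALSE)
    }
    faces[[j]] <- patch
  }

  out <- merge_meshes(c(walls, faces))
  if (nrow(out$vertices) == 0L) {
    warning("resection removed the entire bone")
    return(out)
  }
  weld_vertices(out$vertices, out$faces)
}

#' Extract the resected specimen from a bone mesh
#'
#' The specimen is the bone region on the tumor side of every achieved
#' plane. Built like [resect_bone()] — kept original surface plus one
#' trimmed planar face per plane (oriented outward, i.e. opposite the
#' plane normal) — rather than by repeated capped clipping, which cannot
#' triangulate the non-convex cross-sections arising after earlier cuts.
#'
#' @inheritParams resect_bone
#' @return The specimen [tri_mesh()].
#' @export
carve_specimen <- function(bone, planes, cap_max_edge = 3) {
  check_mesh(bone)
  np <- length(planes)
  walls <- bone
  for (p in planes) {
    if (nrow(walls$vertices) == 0L) break
    walls <- clip_by_plane(walls, check_plane(p), keep = "positive", cap = FALSE)
  }
  faces <- vector("list", np)
  for (j in seq_len(np)) {
    patch <- section_patch(bone, planes[[j]], cap_max_edge)
    if (is.null(patch)) next
    for (i in seq_len(np)) {
      if (i == j || nrow(patch$vertices) == 0L) next
      patch <- clip_by_plane(patch, planes[[i]], keep = "positive", cap = FALSE)
    }
    if (nrow(patch$faces)) patch$faces <- patch$faces[, c(1, 3, 2)]
    faces[[j]] <- patch
  }
  out <- merge_meshes(c(list(walls), faces))
  if (nrow(out$vertices) == 0L) return(out)
  weld_vertices(out$vertices, out$faces)
}

# Triangulated planar patch covering the cross-section of `mesh` at `plane`
# (oriented along +normal), or NULL when the plane misses the mesh.
section_patch <- function(mesh, plane, max_edge = Inf) {
  core <- clip_core(mesh, plane)
  if (!nrow(core$segments)) return(NULL)
  loops <- chain_loops(core$segments[, c(2, 1), drop = FALSE])
  if (!length(loops)) return(NULL)
  capped <- cap_loops(core$vertices, loops, plane$normal, max_edge = max_edge)
  if (!nrow(capped$faces)) return(NULL)
  used <- sort(unique(as.integer(capped$faces)))
  remap <- integer(nrow(capped$vertices))
  remap[used] <- seq_along(used)
  tri_mesh(capped$vertices[used, , drop = FALSE],
           matrix(remap[capped$faces], ncol = 3))
}

#' Simulate a guided resection on a phantom
#'
#' For each target plane of the strategy, draws (or takes) a placement
#' perturbation, forms the achieved cut plane, and removes the specimen plus
#' kerf from the bone. Ground truth (achieved planes, perturbations, cut
#' footprints) is returned for downstream validation.
#'
#' @param bone,tumor watertight [tri_mesh()] phantoms in the pre-operative
#'   frame.
#' @param strategy a [build_strategy()] result.
#' @param noise a [cut_noise()]; ignored when `perturbations` is given.
#' @param perturbations optional data frame with one row per plane and
#'   columns `delta_mm`, `tilt_deg`, `axis_deg` for exact error injection.
#' @param cap_max_edge cut-face cap refinement (mm).
#' @param carve build the remaining-bone and specimen meshes; `FALSE`
#'   simulates the achieved planes only (cheap, for plane-level
#'   calibration studies).
#' @return A list of class `resection_sim`: `remaining_bone`, `specimen`,
#'   `achieved_planes`, `truth` (per-plane data frame), plus the inputs.
#' @export
simulate_resection <- function(bone, tumor, strategy, noise = cut_noise(),
                               perturbations = NULL, cap_max_edge = 3,
                               carve = TRUE) {
  check_mesh(bone); check_mesh(tumor)
  specs <- strategy_specs(strategy)
  np <- length(specs)

  for (s in specs) {
    d <- signed_plane_distance(bone$vertices, s$plane)
    if (min(d) > -1e-9 || max(d) < 1e-9)
      stop("target plane '", s$label, "' does not intersect the bone",
           call. = FALSE)
  }

  if (is.null(perturbations)) {
    kerf <- noise$kerf
    perturbations <- with_seed(noise$seed, data.frame(
      delta_mm = stats::rnorm(np, 0, noise$sigma_t),
      tilt_deg = stats::rnorm(np, 0, noise$sigma_theta),
      axis_deg = stats::runif(np, 0, 360)))
  } else {
    kerf <- if (inherits(noise, "cut_noise")) noise$kerf else 0
    stopifnot(nrow(perturbations) == np,
              all(c("delta_mm", "tilt_deg", "axis_deg") %in% names(perturbations)))
  }

  achieved <- vector("list", np)
  foot_centroid <- matrix(NA_real_, np, 3)
  foot_radius <- numeric(np)
  for (j in seq_len(np)) {
    sec <- plane_section(bone, specs[[j]]$plane)
    if (is.null(sec))
      stop("target plane '", specs[[j]]$label, "' has an empty bone section",
           call. = FALSE)
    foot_centroid[j, ] <- sec$centroid
    foot_radius[j] <- sec$max_radius
    achieved[[j]] <- perturb_plane(specs[[j]]$plane,
                                   delta = perturbations$delta_mm[j],
                                   tilt_deg = perturbations$tilt_deg[j],
                                   axis_deg = perturbations$axis_deg[j],
                                   centroid = sec$centroid)
  }

  remaining <- NULL
  specimen <- NULL
  if (carve) {
    remaining <- resect_bone(bone, achieved, kerf = kerf,
                             cap_max_edge = cap_max_edge)
    specimen <- carve_specimen(bone, achieved, cap_max_edge = cap_max_edge)
  }

  truth <- cbind(data.frame(label = vapply(specs, `[[`, "", "label"),
                            stringsAsFactors = FALSE),
                 perturbations,
                 data.frame(kerf_mm = kerf,
                            footprint_radius_mm = foot_radius))
  truth$footprint_centroid <- foot_centroid

  structure(list(bone = bone, tumor = tumor, strategy = strategy,
                 achieved_planes = achieved, remaining_bone = remaining,
                 specimen = specimen, truth = truth),
            class = "resection_sim")
}

#' Simulate the post-operative scan
#'
#' Applies a rigid displacement (the unknown scanner frame) to the
#' remaining-bone mesh and perturbs every vertex coordinate with i.i.d.
#' Gaussian jitter emulating segmentation error. Deterministic given `seed`.
#'
#' @param postop [tri_mesh()] (normally `remaining_bone` of a simulation).
#' @param transform [rigid3()] pre-op to scan-frame displacement.
#' @param jitter_sd per-coordinate jitter SD (mm, >= 0).
#' @param seed integer seed.
#' @return The scanned [tri_mesh()].
#' @export
apply_scan_noise <- function(postop, transform = rigid3(), jitter_sd = 0,
                             seed = 1) {
  check_mesh(postop)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  out <- apply_rigid(postop, transform)
  if (jitter_sd > 0) {
    nv <- nrow(out$vertices)
    out$vertices <- out$vertices +
      with_seed(seed, matrix(stats::rnorm(3 * nv, 0, jitter_sd), nv, 3))
  }
  out
}

#' Simulate a full case: phantom, cuts, and post-operative scan
#'
#' Convenience wrapper chaining [make_phantom()], [simulate_resection()] and
#' [apply_scan_noise()]. The returned case carries the true scan
#' displacement and its inverse (the true post-op-to-pre-op registration).
#'
#' @param params [phantom_params()].
#' @param strategy a strategy, or `NULL` for a default two-plane strategy at
#'   10 and 12 mm margins.
#' @param noise [cut_noise()].
#' @param perturbations optional exact perturbations (see
#'   [simulate_resection()]).
#' @param displacement [rigid3()] scan displacement (identity by default).
#' @param jitter_sd scan jitter SD (mm).
#' @param seed seed for the scan jitter.
#' @return A list of class `simulated_case`.
#' @export
simulate_case <- function(params = phantom_params(), strategy = NULL,
                          noise = cut_noise(), perturbations = NULL,
                          displacement = rigid3(), jitter_sd = 0, seed = 1) {
  ph <- make_phantom(params)
  if (is.null(strategy))
    strategy <- default_strategy(ph$tumor, margins = c(10, 12))
  sim <- simulate_resection(ph$bone, ph$tumor, strategy, noise = noise,
                            perturbations = perturbations)
  postop <- apply_scan_noise(sim$remaining_bone, displacement, jitter_sd, seed)
  structure(c(sim, list(postop = postop, displacement = displacement,
                        true_registration = invert_rigid(displacement),
                        jitter_sd = jitter_sd)),
            class = c("simulated_case", "resection_sim"))
}
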