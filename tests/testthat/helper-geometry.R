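# Shared fixtures and independent oracles, built in code at test time.

# Independent brute-force oracle for the minimum signed plane distance:
# plain per-vertex arithmetic, no shared code path with the package's
# matrix implementation.
brute_min_signed_distance <- function(mesh, plane) {
  out <- Inf
  for (i in seq_len(nrow(mesh$vertices))) {
    v <- mesh$vertices[i, ]
    d <- (v[1] - plane$anchor[1]) * plane$normal[1] +
      (v[2] - plane$anchor[2]) * plane$normal[2] +
      (v[3] - plane$anchor[3]) * plane$normal[3]
    if (d < out) out <- d
  }
  out
}

# Watertight "random" shape: an icosphere with smooth seeded radial bumps.
random_blob <- function(seed, radius = 10, subdiv = 3) {
  s <- icosphere(subdiv)
  with_seed(seed, {
    amp <- stats::runif(3, 0.5, 2.5)
    dirs <- lapply(1:3, function(i) {
      v <- stats::rnorm(3); v / sqrt(sum(v^2))
    })
    r <- rep(radius, nrow(s$vertices))
    for (i in 1:3) {
      ca <- pmin(1, pmax(-1, s$vertices %*% dirs[[i]]))
      r <- r + amp[i] * exp(-((acos(ca)) / 0.7)^2)
    }
    tri_mesh(s$vertices * as.numeric(r), s$faces)
  })
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# One modest phantom reused across test files (built once per file).
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_phantom(phantom_params(edge_length = 5))
    cache
  }
})

# Ground-truth expected location accuracy for a tilted achieved plane:
# the maximum distance, along the target normal, of the achieved cut
# footprint (the bone's cross-section in the achieved plane) from the
# target plane — sin(theta) times the footprint's lever arm about the
# tilt axis, with the lever arm measured on the plane actually cut.
# Pure plane arithmetic; independent of registration, extraction or
# plane fitting.
tilt_l_oracle <- function(bone, target, achieved) {
  sec <- plane_section(bone, achieved)
  pts <- do.call(rbind, sec$loops)
  max(abs(signed_plane_distance(pts, target)))
}

# Rotation/translation error of a recovered post-op-to-pre-op transform
# against the truth, translation measured at the moving centroid.
transform_errors <- function(estimate, truth, at) {
  rot <- rotation_angle_deg(t(estimate$rotation) %*% truth$rotation)
  tr <- sqrt(sum((apply_rigid(at, estimate) - apply_rigid(at, truth))^2))
  c(rot = rot, trans = tr)
}
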