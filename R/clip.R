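# Plane clipping of triangle meshes. The cut cross-section is recovered as
# directed chord segments (one per crossing triangle), chained into closed
# loops, and fan-triangulated as caps; for a shell-like cross-section the
# hole loops arrive with opposite winding, so signed fan areas and enclosed
# volumes stay exact even though the fans geometrically overlap.

# Clip kept side d <= 0. Returns kept faces, chord segments (directed along
# the kept wall winding), and the (possibly grown) vertex matrix.
clip_core <- function(mesh, plane, tol = 1e-9) {
  V <- mesh$vertices
  F <- mesh$faces
  d <- signed_plane_distance(V, plane)
  # simulation of simplicity: vertices within tol of the plane are treated
  # as strictly on the dropped side, so every cut chord comes from a strict
  # edge crossing and chord chaining never branches at on-plane vertices
  d[abs(d) <= tol] <- tol
  s <- ifelse(d > 0, 1L, -1L)

  sv <- matrix(s[F], ncol = 3)
  keep_whole <- rowSums(sv < 0L) == 3L
  drop_whole <- rowSums(sv > 0L) == 3L
  mixed <- which(!keep_whole & !drop_whole)

  kept_faces <- F[keep_whole, , drop = FALSE]
  new_pts <- list()
  n0 <- nrow(V)
  cache <- new.env(parent = emptyenv())
  seg_a <- integer(0)
  seg_b <- integer(0)
  extra_faces <- list()

  edge_point <- function(i, j) {
    key <- if (i < j) paste0(i, ":", j) else paste0(j, ":", i)
    idx <- cache[[key]]
    if (!is.null(idx)) return(idx)
    t <- d[i] / (d[i] - d[j])
    p <- V[i, ] + t * (V[j, ] - V[i, ])
    new_pts[[length(new_pts) + 1L]] <<- p
    idx <- n0 + length(new_pts)
    cache[[key]] <- idx
    idx
  }

  for (fi in mixed) {
    tri <- F[fi, ]
    poly <- integer(0)
    onpl <- logical(0)
    for (k in 1:3) {
      i <- tri[k]; j <- tri[if (k == 3L) 1L else k + 1L]
      if (s[i] < 0L) { poly <- c(poly, i); onpl <- c(onpl, FALSE) }
      if (s[i] * s[j] < 0L) {
        poly <- c(poly, edge_point(i, j)); onpl <- c(onpl, TRUE)
      }
    }
    np <- length(poly)
    if (np >= 3L) {
      for (k in 2:(np - 1L))
        extra_faces[[length(extra_faces) + 1L]] <- c(poly[1L], poly[k], poly[k + 1L])
    }
    pos <- which(onpl)
    if (length(pos) == 2L && np >= 2L) {
      adj_fwd <- pos[2L] == pos[1L] + 1L
      adj_wrap <- pos[1L] == 1L && pos[2L] == np
      if (adj_fwd) { seg_a <- c(seg_a, poly[pos[1L]]); seg_b <- c(seg_b, poly[pos[2L]]) }
      else if (adj_wrap) { seg_a <- c(seg_a, poly[pos[2L]]); seg_b <- c(seg_b, poly[pos[1L]]) }
    }
  }

  Vout <- if (length(new_pts)) rbind(V, do.call(rbind, new_pts)) else V
  faces <- rbind(kept_faces,
                 if (length(extra_faces)) do.call(rbind, extra_faces))
  segs <- cbind(seg_a, seg_b)
  # drop zero-length chords (triangle touching the plane at a single vertex)
  if (nrow(segs)) segs <- segs[segs[, 1] != segs[, 2], , drop = FALSE]
  list(vertices = Vout, faces = faces, segments = segs)
}

# Chain directed segments into closed loops of vertex ids. Returns a list of
# integer vectors; unmatched chains are dropped with a warning.
chain_loops <- function(segments) {
  if (!nrow(segments)) return(list())
  segments <- unique(segments)
  from <- segments[, 1]
  if (anyDuplicated(from)) {
    warning("non-manifold cut cross-section; dropping ambiguous chords")
    segments <- segments[!duplicated(from), , drop = FALSE]
    from <- segments[, 1]
  }
  to <- segments[, 2]
  used <- rep(FALSE, length(from))
  loops <- list()
  for (k in seq_along(from)) {
    if (used[k]) next
    start <- from[k]
    loop <- integer(0)
    cur <- k
    ok <- FALSE
    for (step in seq_len(length(from) + 1L)) {
      used[cur] <- TRUE
      loop <- c(loop, from[cur])
      nx <- to[cur]
      if (nx == start) { ok <- TRUE; break }
      cur <- match(nx, from)
      if (is.na(cur) || used[cur]) break
    }
    if (ok && length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
    else if (length(loop)) warning("open cut chain discarded (", length(loop),
                                   " chords)")
  }
  loops
}

# 2D even-odd point-in-polygon test.
pip2d <- function(pt, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > pt[2]) != (poly[j, 2] > pt[2]) &&
        pt[1] < (poly[j, 1] - poly[i, 1]) * (pt[2] - poly[i, 2]) /
          (poly[j, 2] - poly[i, 2]) + poly[i, 1])
      inside <- !inside
    j <- i
  }
  inside
}

# Triangulate the planar region bounded by the cut loops, oriented along
# `normal` (loops arrive reversed w.r.t. the wall winding: outer loops
# counter-clockwise, hole loops clockwise). Boundary edges are kept
# verbatim so the cap stays conformal with the walls (no T-junctions);
# with finite `max_edge` the interior gains rings of vertices about that
# far apart (plus a rim ring 0.8 mm inside each boundary) so the cut face
# carries interior vertices for the post-operative surface extraction. A
# disk is filled with concentric rings down to its centroid; an annulus
# (shell cross-section) with rings morphing from the outer loop to the
# hole loop, zipped to both boundaries, so no surface is generated across
# the medullary cavity.
cap_loops <- function(vertices, loops, normal, max_edge = Inf) {
  E <- plane_basis(normal)
  origin <- vertices[loops[[1]][1], ]
  info <- lapply(loops, function(L) {
    P2 <- (vertices[L, , drop = FALSE] -
             matrix(origin, length(L), 3, byrow = TRUE)) %*% E
    k <- length(L)
    jj <- c(2:k, 1L)
    area <- 0.5 * sum(P2[, 1] * P2[jj, 2] - P2[jj, 1] * P2[, 2])
    list(ids = L, p2 = P2, area = area, ctr = colMeans(P2))
  })
  is_outer <- vapply(info, function(x) x$area > 0, logical(1))
  hole_of <- rep(NA_integer_, length(info))
  for (h in which(!is_outer)) {
    for (o in which(is_outer)) {
      if (pip2d(info[[h]]$ctr, info[[o]]$p2)) { hole_of[h] <- o; break }
    }
  }

  to3d <- function(P2) matrix(origin, nrow(P2), 3, byrow = TRUE) + P2 %*% t(E)
  faces <- list()
  want_sign <- numeric(0)
  emit <- function(tri, sgn) {
    faces[[length(faces) + 1L]] <<- tri
    want_sign[length(want_sign) + 1L] <<- sgn
  }

  add_ring_ids <- function(P2) {
    ids <- nrow(vertices) + seq_len(nrow(P2))
    vertices <<- rbind(vertices, to3d(P2))
    ids
  }

  # strip between two same-length rings (ids, aligned by index)
  strip <- function(outer, inner) {
    k <- length(outer)
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      emit(c(outer[i], outer[j], inner[j]), 1)
      emit(c(outer[i], inner[j], inner[i]), 1)
    }
  }

  # band between two rings with different vertex counts: angular merge
  # around `ctr` (both star-shaped about it)
  zipper <- function(ids_a, p2_a, ids_b, p2_b, ctr) {
    th <- function(P) atan2(P[, 2] - ctr[2], P[, 1] - ctr[1])
    oa <- order(th(p2_a)); ob <- order(th(p2_b))
    A <- ids_a[oa]; tA <- th(p2_a)[oa]
    B <- ids_b[ob]; tB <- th(p2_b)[ob]
    na <- length(A); nb <- length(B)
    Ax <- c(A, A[1]); tAx <- c(tA, tA[1] + 2 * pi)
    Bx <- c(B, B[1]); tBx <- c(tB, tB[1] + 2 * pi)
    # start both at their smallest angle
    i <- 1L; j <- 1L
    while (i <= na || j <= nb) {
      adv_a <- if (i > na) FALSE else if (j > nb) TRUE else tAx[i + 1L] <= tBx[j + 1L]
      if (adv_a) { emit(c(Ax[i], Ax[i + 1L], Bx[j]), 1); i <- i + 1L }
      else { emit(c(Ax[i], Bx[j + 1L], Bx[j]), 1); j <- j + 1L }
    }
  }

  # polar radius of a loop, linearly interpolated at grid angles
  polar_radius <- function(P2, ctr, grid) {
    th <- atan2(P2[, 2] - ctr[2], P2[, 1] - ctr[1])
    r <- sqrt(rowSums(sweep(P2, 2, ctr)^2))
    o <- order(th)
    th <- th[o]; r <- r[o]
    stats::approx(c(th, th[1] + 2 * pi), c(r, r[1]), xout = grid,
                  rule = 2)$y
  }

  ring_fracs <- function(gap) {
    if (!is.finite(max_edge)) return(numeric(0))
    nr <- max(1L, ceiling(gap / max_edge))
    f <- seq_len(nr - 1L) / nr
    rim <- 0.8 / gap
    if (rim < 0.5) f <- c(rim, f, 1 - rim)
    sort(unique(round(f, 6)))
  }

  for (o in which(is_outer)) {
    holes <- which(!is_outer & hole_of == o)
    out <- info[[o]]
    if (length(holes) == 0L) {
      # disk: concentric rings down to the centroid
      ctr <- out$ctr
      rmax <- sqrt(max(rowSums(sweep(out$p2, 2, ctr)^2)))
      fr <- ring_fracs(rmax)              # fraction measured from boundary
      radii_scale <- 1 - fr               # ring scale factors, decreasing
      prev_ids <- out$ids
      for (s in radii_scale) {
        P2 <- sweep(sweep(out$p2, 2, ctr) * s, 2, ctr, "+")
        ids <- add_ring_ids(P2)
        strip(prev_ids, ids)
        prev_ids <- ids
      }
      cid <- add_ring_ids(matrix(ctr, 1, 2))
      k <- length(prev_ids)
      for (i in seq_len(k)) {
        j <- if (i == k) 1L else i + 1L
        emit(c(prev_ids[i], prev_ids[j], cid), 1)
      }
    } else if (length(holes) == 1L) {
      # annulus: rings morphing from the outer loop to the hole loop
      hol <- info[[holes]]
      ctr <- hol$ctr
      gap <- mean(sqrt(rowSums(sweep(out$p2, 2, ctr)^2))) -
        mean(sqrt(rowSums(sweep(hol$p2, 2, ctr)^2)))
      fr <- ring_fracs(max(gap, 1e-6))
      if (length(fr)) {
        K <- max(12L, nrow(out$p2))
        grid <- seq(-pi, pi, length.out = K + 1L)[-(K + 1L)]
        r_out <- polar_radius(out$p2, ctr, grid)
        r_hol <- polar_radius(hol$p2, ctr, grid)
        ring_p2 <- lapply(fr, function(t) {
          r <- (1 - t) * r_out + t * r_hol
          cbind(ctr[1] + r * cos(grid), ctr[2] + r * sin(grid))
        })
        ring_ids <- lapply(ring_p2, add_ring_ids)
        if (length(fr) > 1L) for (m in seq_len(length(fr) - 1L))
          strip(ring_ids[[m]], ring_ids[[m + 1L]])
        zipper(out$ids, out$p2, ring_ids[[1L]], ring_p2[[1L]], ctr)
        zipper(ring_ids[[length(fr)]], ring_p2[[length(fr)]],
               hol$ids, hol$p2, ctr)
      } else {
        zipper(out$ids, out$p2, hol$ids, hol$p2, ctr)
      }
    } else {
      # several holes in one outer loop: fall back to overlapping fans
      # (volume-exact; not produced by the packaged phantoms)
      for (L in c(list(out), info[holes])) {
        ctr3 <- colMeans(vertices[L$ids, , drop = FALSE])
        cid <- nrow(vertices) + 1L
        vertices <- rbind(vertices, ctr3)
        k <- length(L$ids)
        sgn <- if (L$area > 0) 1 else -1
        for (i in seq_len(k)) {
          j <- if (i == k) 1L else i + 1L
          emit(c(cid, L$ids[i], L$ids[j]), sgn)
        }
      }
    }
  }
  # orphan holes (no containing outer loop): keep their reversed fans
  for (h in which(!is_outer & is.na(hole_of))) {
    L <- info[[h]]
    ctr3 <- colMeans(vertices[L$ids, , drop = FALSE])
    cid <- nrow(vertices) + 1L
    vertices <- rbind(vertices, ctr3)
    k <- length(L$ids)
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      emit(c(cid, L$ids[i], L$ids[j]), -1)
    }
  }

  if (!length(faces))
    return(list(vertices = vertices, faces = matrix(integer(0), 0, 3)))
  F <- do.call(rbind, faces)
  # enforce the requested orientation per (planar) triangle; coplanarity
  # makes per-triangle flips globally consistent
  a2 <- (vertices[F[, 1], , drop = FALSE] -
           matrix(origin, nrow(F), 3, byrow = TRUE)) %*% E
  b2 <- (vertices[F[, 2], , drop = FALSE] -
           matrix(origin, nrow(F), 3, byrow = TRUE)) %*% E
  c2 <- (vertices[F[, 3], , drop = FALSE] -
           matrix(origin, nrow(F), 3, byrow = TRUE)) %*% E
  sa <- (b2[, 1] - a2[, 1]) * (c2[, 2] - a2[, 2]) -
    (c2[, 1] - a2[, 1]) * (b2[, 2] - a2[, 2])
  flip <- sa * want_sign < 0
  F[flip, ] <- F[flip, c(1, 3, 2)]
  keep <- abs(sa) > 1e-12
  list(vertices = vertices, faces = F[keep, , drop = FALSE])
}

# One midpoint 1-to-4 subdivision round of the faces flagged in `which_faces`
# (all faces by default); midpoints are shared across adjacent triangles.
subdivide_once <- function(vertices, faces, which_faces = NULL) {
  if (is.null(which_faces)) which_faces <- rep(TRUE, nrow(faces))
  cache <- new.env(parent = emptyenv())
  midpoint <- function(i, j) {
    key <- if (i < j) paste0(i, ":", j) else paste0(j, ":", i)
    idx <- cache[[key]]
    if (!is.null(idx)) return(idx)
    vertices <<- rbind(vertices, (vertices[i, ] + vertices[j, ]) / 2)
    idx <- nrow(vertices)
    cache[[key]] <- idx
    idx
  }
  out <- vector("list", nrow(faces))
  for (fi in seq_len(nrow(faces))) {
    f <- faces[fi, ]
    if (!which_faces[fi]) { out[[fi]] <- matrix(f, 1, 3); next }
    m12 <- midpoint(f[1], f[2]); m23 <- midpoint(f[2], f[3]); m31 <- midpoint(f[3], f[1])
    out[[fi]] <- rbind(c(f[1], m12, m31), c(f[2], m23, m12),
                       c(f[3], m31, m23), c(m12, m23, m31))
  }
  list(vertices = vertices, faces = do.call(rbind, out))
}

#' Clip a mesh by a plane
#'
#' Returns the part of the mesh on the requested side of the plane, with the
#' cut cross-section triangulated ("capped") so that watertight inputs give
#' watertight outputs and enclosed volume is conserved across the two sides.
#'
#' @param mesh a [tri_mesh()].
#' @param plane a [plane3()].
#' @param keep `"negative"` keeps the side the normal points away from (the
#'   remaining bone under the package orientation convention); `"positive"`
#'   keeps the specimen side.
#' @param cap triangulate the cut cross-section (requires a watertight input
#'   for a closed result).
#' @param cap_max_edge target spacing (mm) of the radial rings triangulating
#'   the cap interior; `Inf` leaves a plain centroid fan. Finite values give
#'   the cut face interior vertices, which the post-operative cut-surface
#'   extraction relies on.
#' @param tol on-plane tolerance (mm).
#' @return A [tri_mesh()]; empty if the kept side is empty, the input mesh
#'   if the plane misses it entirely.
#' @export
clip_by_plane <- function(mesh, plane, keep = c("negative", "positive"),
                          cap = TRUE, cap_max_edge = Inf, tol = 1e-9) {
  check_mesh(mesh, nonempty = FALSE)
  keep <- match.arg(keep)
  if (nrow(mesh$vertices) == 0L) return(mesh)
  check_plane(plane)
  pl <- if (keep == "positive") plane3(plane$anchor, -plane$normal) else plane
  d <- signed_plane_distance(mesh$vertices, pl)
  if (all(d <= tol)) return(mesh)
  if (all(d >= -tol)) return(tri_mesh(NULL, NULL))

  core <- clip_core(mesh, pl, tol)
  verts <- core$vertices
  faces <- core$faces
  if (cap && nrow(core$segments)) {
    loops <- chain_loops(core$segments[, c(2, 1), drop = FALSE])
    capped <- cap_loops(verts, loops, pl$normal, max_edge = cap_max_edge)
    verts <- capped$vertices
    faces <- rbind(faces, capped$faces)
  }
  if (is.null(faces) || nrow(faces) == 0L) return(tri_mesh(NULL, NULL))
  used <- sort(unique(as.integer(faces)))
  remap <- integer(nrow(verts))
  remap[used] <- seq_along(used)
  tri_mesh(verts[used, , drop = FALSE], matrix(remap[faces], ncol = 3))
}

#' Planar cross-section of a mesh
#'
#' Intersects a closed mesh with a plane and returns the boundary loops of
#' the cross-section, its signed area and its area centroid (all in the
#' cutting plane). Used to find the footprint of a planned cut on the bone.
#'
#' @param mesh a watertight [tri_mesh()].
#' @param plane a [plane3()].
#' @return A list with `loops` (list of k x 3 point matrices), `area`
#'   (mm^2, holes subtracted), `centroid` (3-vector) and `max_radius`
#'   (largest centroid-to-boundary distance, mm). `NULL` if the plane misses
#'   the mesh.
#' @export
plane_section <- function(mesh, plane, tol = 1e-9) {
  check_mesh(mesh)
  check_plane(plane)
  core <- clip_core(mesh, plane, tol)
  if (!nrow(core$segments)) return(NULL)
  loops <- chain_loops(core$segments[, c(2, 1), drop = FALSE])
  if (!length(loops)) return(NULL)
  n <- plane$normal
  tot_a <- 0
  cent_acc <- c(0, 0, 0)
  pts_all <- NULL
  loop_pts <- list()
  for (loop in loops) {
    P <- core$vertices[loop, , drop = FALSE]
    loop_pts[[length(loop_pts) + 1L]] <- P
    c0 <- colMeans(P)
    k <- nrow(P)
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      a <- 0.5 * sum(cross3(P[i, ] - c0, P[j, ] - c0) * n)
      tot_a <- tot_a + a
      cent_acc <- cent_acc + a * (c0 + P[i, ] + P[j, ]) / 3
    }
    pts_all <- rbind(pts_all, P)
  }
  if (abs(tot_a) < 1e-12) return(NULL)
  centroid <- unname(cent_acc / tot_a)
  rmax <- sqrt(max(rowSums((pts_all -
            matrix(centroid, nrow(pts_all), 3, byrow = TRUE))^2)))
  list(loops = loop_pts, area = tot_a, centroid = centroid, max_radius = rmax)
}
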