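# Identification of achieved cut surfaces on the registered post-operative
# model and computation of the accuracy metrics: achieved surgical margin
# SM (minimum signed distance from the achieved cut plane to the tumor
# boundary), error in safe margin ESM = SM - desired margin, and the
# ISO1101-style location accuracy L (maximum distance between achieved cut
# and target plane, measured along the target normal over the physical cut
# footprint).

#' Total-least-squares plane fit
#'
#' Fits the plane minimizing orthogonal distances (centroid plus
#' smallest-variance principal direction). The normal sign is chosen toward
#' `orient_toward` when given (normally the matched target plane's normal,
#' so the fitted plane follows the tumor-side orientation convention).
#'
#' @param points n x 3 matrix, n >= 3, not collinear.
#' @param orient_toward optional 3-vector; the fitted normal is flipped to
#'   have a positive dot product with it.
#' @return List with `plane` ([plane3()]) and `rms` (orthogonal residual
#'   RMS, mm).
#' @export
fit_plane <- function(points, orient_toward = NULL) {
  P <- as_points_matrix(points)
  if (nrow(P) < 3L) stop("need at least 3 points to fit a plane", call. = FALSE)
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr), nu = 0)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12))
    stop("points are collinear or degenerate; no unique plane", call. = FALSE)
  normal <- sv$v[, 3]
  if (!is.null(orient_toward) && sum(normal * orient_toward) < 0)
    normal <- -normal
  list(plane = plane3(ctr, normal), rms = sv$d[3] / sqrt(nrow(P)))
}

#' Extract achieved cut surfaces from a registered post-operative model
#'
#' Post-operative vertices farther than `novelty_threshold` from the
#' pre-operative surface are "new" surface created by the saw. New points
#' are partitioned into planar clusters by a seeded consensus (RANSAC-style)
#' plane search with inlier band `inlier_threshold`, each cluster refit by
#' total least squares, and matched to the target plane with the most
#' similar normal and the smallest centroid-to-plane distance. Targets with
#' no matching cluster are reported as missing, not as an error; two
#' non-coplanar clusters claiming one target are an error naming the
#' candidates.
#'
#' @param postop_registered [tri_mesh()] already registered to the pre-op
#'   frame.
#' @param preop pre-operative bone [tri_mesh()].
#' @param strategy the [build_strategy()] result.
#' @param novelty_threshold distance above which a post-op vertex counts as
#'   new surface (mm).
#' @param inlier_threshold planarity inlier band for the consensus search
#'   (mm).
#' @param min_points smallest accepted cluster size.
#' @param max_angle_deg largest normal deviation for cluster-target
#'   matching (degrees).
#' @param trials consensus draws per cluster.
#' @param seed integer seed for the consensus search.
#' @return List of class `achieved_cuts` with one entry per target plane:
#'   either an `achieved_cut` (fields `points`, `plane`, `rms`,
#'   `target_index`, `n_points`) or `NULL` when missing.
#' @export
extract_cut_surfaces <- function(postop_registered, preop, strategy,
                                 novelty_threshold = 0.5,
                                 inlier_threshold = 0.3,
                                 min_points = 25, max_angle_deg = 25,
                                 trials = 300, seed = 1) {
  check_mesh(postop_registered); check_mesh(preop)
  specs <- strategy_specs(strategy)
  d <- surface_distance(postop_registered$vertices, preop)
  novel <- d > novelty_threshold
  pts <- postop_registered$vertices[novel, , drop = FALSE]
  nrmls <- vertex_normals(postop_registered)[novel, , drop = FALSE]
  cos_lim <- cos(35 * pi / 180)
  # only points whose surface normal is compatible with some target plane
  # can belong to a cut face; this drops cap-rim vertices with mixed
  # wall/cap normals that would otherwise seed spurious clusters
  if (nrow(pts)) {
    compat <- rep(FALSE, nrow(pts))
    for (s in specs)
      compat <- compat | abs(as.numeric(nrmls %*% s$plane$normal)) >= cos_lim
    pts <- pts[compat, , drop = FALSE]
    nrmls <- nrmls[compat, , drop = FALSE]
  }

  clusters <- list()
  max_clusters <- length(specs) + 2L
  with_seed(seed, {
    while (nrow(pts) >= min_points && length(clusters) < max_clusters) {
      best_n <- 0L
      best_in <- NULL
      for (t in seq_len(trials)) {
        tri <- pts[sample.int(nrow(pts), 3L), , drop = FALSE]
        nrm <- cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
        if (vnorm(nrm) < 1e-9) next
        pl <- plane3(tri[1, ], nrm)
        # inliers must be close to the plane AND oriented like it, so
        # points of an adjacent cut face near the planes' intersection
        # line cannot contaminate the cluster
        inl <- abs(signed_plane_distance(pts, pl)) <= inlier_threshold &
          abs(as.numeric(nrmls %*% pl$normal)) >= cos_lim
        if (sum(inl) > best_n) { best_n <- sum(inl); best_in <- inl }
      }
      if (best_n < min_points) break
      for (r in 1:2) {   # TLS refit and re-select inliers
        ft <- fit_plane(pts[best_in, , drop = FALSE])
        best_in <- abs(signed_plane_distance(pts, ft$plane)) <= inlier_threshold &
          abs(as.numeric(nrmls %*% ft$plane$normal)) >= cos_lim
      }
      ft <- fit_plane(pts[best_in, , drop = FALSE])
      clusters[[length(clusters) + 1L]] <-
        list(points = pts[best_in, , drop = FALSE], plane = ft$plane,
             rms = ft$rms)
      pts <- pts[!best_in, , drop = FALSE]
      nrmls <- nrmls[!best_in, , drop = FALSE]
    }
  })

  # match clusters to target planes by normal similarity, then proximity
  assign_to <- integer(length(clusters))
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    ctr <- colMeans(cl$points)
    ang <- vapply(specs, function(s)
      acos(pmin(1, abs(sum(cl$plane$normal * s$plane$normal)))) * 180 / pi,
      numeric(1))
    off <- vapply(specs, function(s)
      abs(signed_plane_distance(ctr, s$plane)), numeric(1))
    cand <- which(ang <= max_angle_deg)
    assign_to[ci] <- if (length(cand)) cand[which.min(off[cand])] else 0L
  }

  out <- vector("list", length(specs))
  for (j in seq_along(specs)) {
    mine <- which(assign_to == j)
    if (!length(mine)) next
    if (length(mine) > 1L) {
      # coplanar fragments of one cut face are merged (the union must
      # still fit one plane); small debris clusters are dropped; two
      # comparable non-coplanar clusters are a genuine ambiguity
      sizes <- vapply(clusters[mine], function(cl) nrow(cl$points), 0L)
      merged <- do.call(rbind, lapply(clusters[mine], `[[`, "points"))
      ok <- fit_plane(merged)$rms <= inlier_threshold
      if (!ok) {
        main <- mine[which.max(sizes)]
        minor <- setdiff(mine, main)
        if (all(sizes[match(minor, mine)] < 0.25 * max(sizes))) {
          merged <- clusters[[main]]$points
        } else {
          stop("ambiguous cut-surface match for plane '", specs[[j]]$label,
               "': ", length(mine), " non-coplanar clusters of sizes ",
               paste(sizes, collapse = ", "), call. = FALSE)
        }
      }
    } else merged <- clusters[[mine]]$points
    ft <- fit_plane(merged, orient_toward = specs[[j]]$plane$normal)
    out[[j]] <- structure(list(points = merged, plane = ft$plane,
                               rms = ft$rms, target_index = j,
                               n_points = nrow(merged)),
                          class = "achieved_cut")
  }
  names(out) <- vapply(specs, `[[`, "", "label")
  structure(out, class = "achieved_cuts")
}

#' Achieved surgical margin SM
#'
#' Minimum distance (mm) between the achieved cut plane and the tumor
#' boundary, signed by the orientation convention: positive = clear margin,
#' negative = the plane penetrates the tumor (a geometric intralesional
#' cut).
#'
#' @param cut an `achieved_cut` (or a bare [plane3()]).
#' @param tumor watertight [tri_mesh()].
#' @return SM (mm).
#' @export
surgical_margin <- function(cut, tumor) {
  pl <- if (is_plane3(cut)) cut else cut$plane
  check_mesh(tumor, what = "tumor")
  min_signed_distance_to_plane(tumor, pl)
}

#' Error in safe margin ESM
#'
#' `ESM = SM - desired margin`: negative for cutting under the desired safe
#' margin, positive for cutting over it. `NA` desired margin (margin-free
#' plane) gives `NA`.
#'
#' @param sm achieved surgical margin (mm).
#' @param desired desired safe margin (mm) or `NA`.
#' @return ESM (mm).
#' @export
error_in_safe_margin <- function(sm, desired) {
  ifelse(is.na(desired), NA_real_, sm - desired)
}

#' Location accuracy L
#'
#' ISO1101-style location tolerance of the achieved cut: the maximum
#' absolute distance, measured along the target plane's normal, from the
#' extracted cut-surface points to the target plane. Evaluated over the
#' physical cut footprint (a tilted infinite plane would have unbounded
#' maximum distance).
#'
#' @param cut an `achieved_cut` (its `points` are used), or a bare n x 3
#'   point matrix.
#' @param target the target [plane3()].
#' @return L (mm, >= 0).
#' @export
location_accuracy <- function(cut, target) {
  pts <- if (is.matrix(cut)) cut else cut$points
  if (is.null(pts) || nrow(pts) < 1L)
    stop("cut has no surface points", call. = FALSE)
  max(abs(signed_plane_distance(pts, target)))
}

#' Kerf correction of the location accuracy
#'
#' When the cutting guide sits on the tumor side of the plane, the saw
#' blade's kerf displaces the remaining-bone cut face by the blade
#' thickness, which must be subtracted from the raw location accuracy
#' (floored at zero). With the guide on the remaining-bone side the raw
#' value is returned unchanged.
#'
#' @param l_raw raw location accuracy (mm).
#' @param blade_thickness saw blade thickness (mm, >= 0).
#' @param guide_on_tumor_side logical flag.
#' @return Corrected L (mm).
#' @export
kerf_correct <- function(l_raw, blade_thickness, guide_on_tumor_side) {
  if (any(blade_thickness < 0)) stop("blade thickness must be >= 0", call. = FALSE)
  ifelse(guide_on_tumor_side, pmax(l_raw - blade_thickness, 0), l_raw)
}

#' UICC-style margin class from the geometric SM
#'
#' R0 (in sano) for SM > 1 mm, R1 (possible microscopic residuals) for SM
#' between 0 and 1 mm, "intralesional" for SM < 0 (the geometric proxy of a
#' cut through the tumor; histologic R2 depends on the specimen and is not
#' derivable from geometry). `NA` margins give `"n/a"`.
#'
#' @param sm achieved surgical margin (mm), vectorized.
#' @return Character vector of classes.
#' @export
classify_margin <- function(sm) {
  ifelse(is.na(sm), "n/a",
         ifelse(sm > 1, "R0", ifelse(sm >= 0, "R1", "intralesional")))
}

#' Evaluate a case end to end
#'
#' Registers the post-operative model (unless a registration is supplied),
#' extracts the achieved cut surfaces, and computes one evaluation record
#' per target plane: SM, ESM, kerf-corrected L and the margin class.
#' Margin-free planes report L only. Unmatched targets yield a record with
#' `matched = FALSE` and `NA` metrics.
#'
#' @param preop pre-operative bone [tri_mesh()].
#' @param tumor tumor [tri_mesh()].
#' @param strategy the [build_strategy()] result.
#' @param postop post-operative bone [tri_mesh()] (arbitrary rigid frame).
#' @param registration a [rigid3()], an `icp_result`, or `NULL` to run
#'   [icp_register()] internally.
#' @param blade_thickness saw blade thickness for the kerf correction (mm).
#' @param guide_on_tumor_side logical, recycled over planes: was the guide
#'   on the tumor side (kerf correction applies)?
#' @param icp icp parameters used when `registration` is `NULL`.
#' @param ... passed to [extract_cut_surfaces()].
#' @return A data frame of class `evaluation_records` with columns
#'   `plane_label`, `desired_margin_mm`, `sm_mm`, `esm_mm`, `l_mm`,
#'   `kerf_corrected`, `margin_class`, `matched`, `n_points`, `fit_rms_mm`;
#'   the registration used is attached as attribute `registration`.
#' @export
evaluate_case <- function(preop, tumor, strategy, postop, registration = NULL,
                          blade_thickness = 0, guide_on_tumor_side = FALSE,
                          icp = icp_params(), ...) {
  check_mesh(preop); check_mesh(tumor); check_mesh(postop)
  specs <- strategy_specs(strategy)
  np <- length(specs)
  if (is.null(registration)) registration <- icp_register(postop, preop, icp)
  reg_T <- if (inherits(registration, "icp_result")) registration$transform
           else registration
  if (!is_rigid3(reg_T)) stop("registration must be rigid3 or icp_result",
                              call. = FALSE)
  postop_reg <- apply_rigid(postop, reg_T)
  cuts <- extract_cut_surfaces(postop_reg, preop, strategy, ...)
  guide_flag <- rep_len(as.logical(guide_on_tumor_side), np)

  rows <- vector("list", np)
  for (j in seq_len(np)) {
    s <- specs[[j]]
    cut <- cuts[[j]]
    if (is.null(cut)) {
      rows[[j]] <- data.frame(plane_label = s$label,
                              desired_margin_mm = s$desired_safe_margin,
                              sm_mm = NA_real_, esm_mm = NA_real_,
                              l_mm = NA_real_, kerf_corrected = FALSE,
                              margin_class = "n/a", matched = FALSE,
                              n_points = 0L, fit_rms_mm = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    margin_free <- is.na(s$desired_safe_margin)
    sm <- if (margin_free) NA_real_ else surgical_margin(cut, tumor)
    esm <- error_in_safe_margin(sm, s$desired_safe_margin)
    l_raw <- location_accuracy(cut, s$plane)
    l <- kerf_correct(l_raw, blade_thickness, guide_flag[j])
    rows[[j]] <- data.frame(plane_label = s$label,
                            desired_margin_mm = s$desired_safe_margin,
                            sm_mm = sm, esm_mm = esm, l_mm = l,
                            kerf_corrected = guide_flag[j] && blade_thickness > 0,
                            margin_class = classify_margin(sm),
                            matched = TRUE, n_points = cut$n_points,
                            fit_rms_mm = cut$rms, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_records", class(out))
  attr(out, "registration") <- registration
  out
}
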