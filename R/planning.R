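# Resection strategy construction: target planes placed at a desired safe
# margin around the tumor, validation of the planned margins, and cutting
# depth calibration. The interactive placement a surgeon performs in a
# visualization tool is replaced by a deterministic support-plane
# constructor along a chosen approach direction.

#' Target plane tangent to the tumor at a safe margin
#'
#' Returns the supporting plane of the tumor in `-direction`, offset away
#' from the tumor by `margin`, with normal `+direction` (toward the tumor,
#' the package orientation convention). By construction
#' `planned_margin(plane, tumor) == margin` exactly.
#'
#' @param tumor watertight [tri_mesh()].
#' @param direction approach direction (3-vector, normalized internally);
#'   the plane normal.
#' @param margin desired safe margin (mm, >= 0).
#' @return A [plane3()].
#' @export
tangent_plane_at_margin <- function(tumor, direction, margin) {
  check_mesh(tumor, what = "tumor")
  if (margin < 0) stop("margin must be >= 0", call. = FALSE)
  d <- unitize(direction)
  proj <- as.numeric(tumor$vertices %*% d)
  vmin <- tumor$vertices[which.min(proj), ]
  plane3(vmin - margin * d, d)
}

#' Planned safe margin of a target plane
#'
#' Minimum signed distance from the plane to the tumor: the margin the plan
#' would achieve if the cut were executed exactly. Identical mathematics to
#' the achieved surgical margin, applied to the target plane.
#'
#' @param plane target [plane3()] (normal toward the tumor).
#' @param tumor watertight [tri_mesh()].
#' @return Margin (mm); negative when the plane penetrates the tumor.
#' @export
planned_margin <- function(plane, tumor) {
  check_mesh(tumor, what = "tumor")
  min_signed_distance_to_plane(tumor, plane)
}

#' Specification of one target plane
#'
#' Couples a target plane with the surgeon's desired safe margin. Margins in
#' clinical use run 3-15 mm; values below 3 mm trigger a warning. A missing
#' margin (`NA`) marks a margin-free plane (e.g. an extra-articular
#' resection plane not referenced to the tumor), for which evaluation
#' reports the location accuracy only.
#'
#' @param plane a [plane3()].
#' @param desired_safe_margin mm (> 0), or `NA` for a margin-free plane.
#' @param label plane label used in reports.
#' @return A list of class `target_spec`.
#' @export
target_plane_spec <- function(plane, desired_safe_margin = NA_real_,
                              label = "plane") {
  check_plane(plane)
  m <- desired_safe_margin
  if (!is.na(m)) {
    if (m <= 0) stop("desired safe margin must be positive (or NA)", call. = FALSE)
    if (m < 3) warning("desired safe margin below 3 mm (plane '", label, "')")
  }
  structure(list(plane = plane, desired_safe_margin = as.numeric(m),
                 label = as.character(label)), class = "target_spec")
}

#' Build and validate a resection strategy
#'
#' A strategy is an ordered list of 1 to 6 target planes. When the tumor is
#' supplied, each plane with a desired margin is checked: its planned margin
#' must not fall short of the desired one (an unsafely placed plane is an
#' error).
#'
#' @param specs list of [target_plane_spec()] objects.
#' @param tumor optional watertight [tri_mesh()] for margin validation.
#' @param case_id optional case metadata string.
#' @return A list of class `resection_strategy`.
#' @export
build_strategy <- function(specs, tumor = NULL, case_id = NULL) {
  if (inherits(specs, "target_spec")) specs <- list(specs)
  n <- length(specs)
  if (n < 1L || n > 6L)
    stop("a resection strategy must have 1 to 6 planes (got ", n, ")",
         call. = FALSE)
  for (s in specs) if (!inherits(s, "target_spec"))
    stop("all specs must be 'target_spec' objects", call. = FALSE)
  labels <- vapply(specs, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("plane labels must be unique", call. = FALSE)
  if (!is.null(tumor)) {
    for (s in specs) {
      if (is.na(s$desired_safe_margin)) next
      pm <- planned_margin(s$plane, tumor)
      if (pm < s$desired_safe_margin - 1e-6)
        stop("plane '", s$label, "' is unsafely placed: planned margin ",
             sprintf("%.2f", pm), " mm < desired ",
             sprintf("%.2f", s$desired_safe_margin), " mm", call. = FALSE)
    }
  }
  structure(list(specs = specs, case_id = case_id),
            class = "resection_strategy")
}

#' Access the target-plane specs of a strategy
#'
#' @param strategy a [build_strategy()] result.
#' @return The ordered list of [target_plane_spec()] objects.
#' @export
strategy_specs <- function(strategy) {
  if (!inherits(strategy, "resection_strategy"))
    stop("expected a 'resection_strategy'", call. = FALSE)
  strategy$specs
}

#' @export
length.resection_strategy <- function(x) length(x$specs)

#' @export
print.resection_strategy <- function(x, ...) {
  cat(sprintf("<resection_strategy> %d plane(s)\n", length(x$specs)))
  for (s in x$specs)
    cat(sprintf("  %-10s margin %s mm\n", s$label,
                ifelse(is.na(s$desired_safe_margin), "-",
                       format(s$desired_safe_margin))))
  invisible(x)
}

#' Default multi-directional strategy around a tumor
#'
#' Places up to six tangent target planes along the coordinate directions
#' (+x, -x, +y, -y, +z, -z) at the given margins.
#'
#' @param tumor watertight [tri_mesh()].
#' @param margins numeric vector (1-6) of desired safe margins (mm).
#' @param directions optional matrix of approach directions (rows), one per
#'   margin.
#' @return A [build_strategy()] result.
#' @export
default_strategy <- function(tumor, margins = c(10, 12), directions = NULL) {
  if (is.null(directions))
    directions <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  n <- length(margins)
  if (n > nrow(directions)) stop("not enough directions", call. = FALSE)
  specs <- lapply(seq_len(n), function(j)
    target_plane_spec(tangent_plane_at_margin(tumor, directions[j, ], margins[j]),
                      desired_safe_margin = margins[j],
                      label = paste0("P", j)))
  build_strategy(specs, tumor = tumor)
}

#' Cutting depth along a direction line in the cut plane
#'
#' The calibration value engraved on a cutting guide: the largest distance
#' `t >= 0` along `direction` from `edge_point` at which the ray still meets
#' the bone cross-section in the plane (the "deepest bone structure to be
#' cut"). Zero when the ray never meets bone.
#'
#' @param bone watertight [tri_mesh()].
#' @param plane cutting [plane3()].
#' @param edge_point 3-vector on the plane (the guide's outer edge).
#' @param direction unit 3-vector lying in the plane.
#' @return Depth (mm).
#' @export
cutting_depth <- function(bone, plane, edge_point, direction) {
  check_mesh(bone)
  check_plane(plane)
  dirn <- unitize(direction)
  if (abs(sum(dirn * plane$normal)) > 1e-6)
    stop("direction must lie in the cutting plane", call. = FALSE)
  edge_point <- as_point3(edge_point)
  sec <- plane_section(bone, plane)
  if (is.null(sec)) return(0)
  E <- plane_basis(plane$normal)
  o2 <- as.numeric(t(E) %*% (edge_point - plane$anchor))
  d2 <- as.numeric(t(E) %*% dirn)
  tmax <- 0
  for (P in sec$loops) {
    Q <- (P - matrix(plane$anchor, nrow(P), 3, byrow = TRUE)) %*% E
    k <- nrow(Q)
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      # solve o2 + t d2 = Q[i] + u (Q[j] - Q[i])
      e <- Q[j, ] - Q[i, ]
      det <- d2[1] * (-e[2]) - d2[2] * (-e[1])
      if (abs(det) < 1e-12) next
      rhs <- Q[i, ] - o2
      t <- (rhs[1] * (-e[2]) - rhs[2] * (-e[1])) / det
      u <- (d2[1] * rhs[2] - d2[2] * rhs[1]) / det
      if (u >= -1e-9 && u <= 1 + 1e-9 && t >= -1e-9) tmax <- max(tmax, t)
    }
  }
  tmax
}

#' Strategy JSON serialization
#'
#' Strategies are exchanged as a JSON list of
#' `{"label", "anchor", "normal", "desired_safe_margin_mm"}` objects
#' (margin `null` for margin-free planes), coordinates in mm.
#'
#' @param strategy a [build_strategy()] result.
#' @param path file path.
#' @return `read_strategy_json()` returns a `resection_strategy` (not
#'   re-validated against a tumor).
#' @export
write_strategy_json <- function(strategy, path) {
  specs <- strategy_specs(strategy)
  obj <- lapply(specs, function(s) list(
    label = s$label,
    anchor = unname(s$plane$anchor),
    normal = unname(s$plane$normal),
    desired_safe_margin_mm = if (is.na(s$desired_safe_margin)) NULL
                             else s$desired_safe_margin))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_strategy_json
#' @export
read_strategy_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  specs <- lapply(obj, function(s) {
    m <- s$desired_safe_margin_mm
    target_plane_spec(plane3(unlist(s$anchor), unlist(s$normal)),
                      desired_safe_margin = if (is.null(m)) NA_real_ else m,
                      label = s$label)
  })
  build_strategy(specs)
}
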