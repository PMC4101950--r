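# Rigid registration of the post-operative bone model to the pre-operative
# model: principal-axes pre-alignment followed by trimmed ICP with
# point-to-surface correspondences. Trimming makes the registration robust
# to partial overlap — the post-operative model lacks the resected specimen
# and may carry regrown or artefactual surface.

#' Trimmed ICP parameters
#'
#' @param max_iter maximum ICP iterations.
#' @param tol convergence tolerance on the change of trimmed RMS (mm).
#' @param trim minimum fraction of worst correspondences discarded each
#'   iteration (0 to < 0.5); the default 0.2 tolerates the missing
#'   specimen. The effective trim is tuned per iteration between this and
#'   0.5 by the fractional criterion (trimmed RMS divided by the cube of
#'   the kept fraction), so the cut faces — new surface with no
#'   pre-operative counterpart — drop out without hand-setting the overlap.
#' @param sample number of moving-surface points used as correspondences
#'   (a fixed, seeded vertex subset for determinism).
#' @param seed integer seed for the correspondence sample.
#' @return A list of class `icp_params`.
#' @export
icp_params <- function(max_iter = 50, tol = 1e-4, trim = 0.2, sample = 500,
                       seed = 1) {
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)", call. = FALSE)
  structure(list(max_iter = as.integer(max_iter), tol = tol, trim = trim,
                 sample = as.integer(sample), seed = as.integer(seed)),
            class = "icp_params")
}

# Principal axes of a vertex cloud with skewness-based sign disambiguation.
principal_frame <- function(V) {
  ctr <- colMeans(V)
  Vc <- sweep(V, 2, ctr)
  ev <- eigen(crossprod(Vc) / nrow(Vc), symmetric = TRUE)
  A <- ev$vectors           # columns, decreasing eigenvalue
  skew <- numeric(3)
  for (i in 1:3) {
    p <- Vc %*% A[, i]
    skew[i] <- mean(p^3)
    if (skew[i] < 0) { A[, i] <- -A[, i]; skew[i] <- -skew[i] }
  }
  if (det(A) < 0) {
    i <- which.min(skew)    # flip the least-committed axis
    A[, i] <- -A[, i]
  }
  list(center = ctr, axes = A, values = ev$values, skew = skew)
}

#' Coarse alignment by centroids and principal axes
#'
#' Translates the moving mesh's centroid onto the fixed one and aligns
#' their principal axes, disambiguating axis signs with third central
#' moments. Falls back to a centroid-only translation (with a warning) for
#' degenerate vertex distributions. Deterministic.
#'
#' Principal axes carry an inherent four-fold proper sign ambiguity; the
#' skewness disambiguation resolves it for intact shapes, but a
#' post-operative model missing its specimen can flip a moment.
#' `candidates = TRUE` therefore returns all four proper-rotation
#' alignments (skewness-preferred first), among which [icp_register()]
#' selects by trimmed residual.
#'
#' @param moving,fixed [tri_mesh()] objects.
#' @param candidates return all four proper axis-sign alignments instead of
#'   the single skewness-disambiguated one.
#' @return A [rigid3()] mapping `moving` into the `fixed` frame, or a list
#'   of four when `candidates = TRUE`.
#' @export
initial_align <- function(moving, fixed, candidates = FALSE) {
  check_mesh(moving); check_mesh(fixed)
  fm <- principal_frame(moving$vertices)
  ff <- principal_frame(fixed$vertices)
  degenerate <- min(fm$values) < 1e-10 * max(fm$values) ||
    min(ff$values) < 1e-10 * max(ff$values)
  if (degenerate) {
    warning("degenerate vertex distribution; centroid-only alignment")
    tr <- rigid3(diag(3), ff$center - fm$center)
    return(if (candidates) list(tr) else tr)
  }
  if (!candidates) {
    R <- ff$axes %*% t(fm$axes)
    if (det(R) < 0) R <- ff$axes %*% diag(c(1, 1, -1)) %*% t(fm$axes)
    return(rigid3(R, ff$center - as.numeric(R %*% fm$center)))
  }
  # all proper axis correspondences whose eigenvalues are comparable: a
  # partially resected model can swap near-degenerate principal axes, so
  # sign flips alone do not cover the pre-alignment ambiguity
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  parity <- c(1, -1, -1, 1, 1, -1)
  even_signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  odd_signs <- list(c(-1, 1, 1), c(1, -1, 1), c(1, 1, -1), c(-1, -1, -1))
  out <- list()
  for (pi in seq_along(perms)) {
    p <- perms[[pi]]
    ratio <- fm$values / ff$values[p]
    if (any(ratio < 0.25 | ratio > 4)) next
    for (s in (if (parity[pi] > 0) even_signs else odd_signs)) {
      R <- ff$axes[, p] %*% diag(s) %*% t(fm$axes)
      out[[length(out) + 1L]] <-
        rigid3(R, ff$center - as.numeric(R %*% fm$center))
    }
  }
  out
}

# Least-squares rigid motion P -> Q (Kabsch with reflection guard).
kabsch <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  H <- crossprod(sweep(P, 2, pc), sweep(Q, 2, qc))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid3(R, qc - as.numeric(R %*% pc))
}

# Incremental point-to-plane step: small rigid motion (omega, t) minimizing
# sum over i of (n_i . (p_i + omega x p_i + t - q_i))^2, applied exactly via
# Rodrigues. Point-to-plane updates do not stall on tangential sliding the
# way point-to-point (Kabsch) updates do on smooth, nearly symmetric bone.
point_to_plane_step <- function(P, Q, N) {
  A <- cbind(cross3_rows(P, N), N)
  r <- rowSums(N * (P - Q))
  M <- crossprod(A)
  rhs <- -crossprod(A, r)
  x <- tryCatch(solve(M, rhs), error = function(e) NULL)
  if (is.null(x)) return(NULL)
  w <- x[1:3]
  ang <- sqrt(sum(w^2))
  R <- if (ang < 1e-12) diag(3) else
    rotation_about_axis(w / ang, ang * 180 / pi)
  rigid3(R, x[4:6])
}

#' Trimmed iterative closest point registration
#'
#' Starting from [initial_align()], iterates: transform a fixed seeded
#' sample of moving vertices, find each point's closest point on the fixed
#' surface, discard the `trim` fraction with the largest residuals, and
#' re-solve the least-squares rigid motion. The trimmed RMS is
#' non-increasing across iterations; on hitting `max_iter` without meeting
#' `tol` the best transform so far is returned with `converged = FALSE`
#' (never an exception).
#'
#' @param moving,fixed [tri_mesh()] objects (moving is registered onto
#'   fixed).
#' @param params an [icp_params()].
#' @return A list of class `icp_result`: `transform` ([rigid3()]), `rms`
#'   (final trimmed RMS, mm), `converged`, `iterations`, `rms_log`.
#' @export
icp_register <- function(moving, fixed, params = icp_params()) {
  check_mesh(moving); check_mesh(fixed)
  if (!inherits(params, "icp_params")) stop("expected 'icp_params'", call. = FALSE)
  starts <- initial_align(moving, fixed, candidates = TRUE)
  n <- nrow(moving$vertices)
  # area-weighted: uniform over the surface, not over the triangulation
  w <- vertex_areas(moving)
  if (sum(w) <= 0) w <- rep(1, n)
  idx <- with_seed(params$seed,
                   sample.int(n, min(params$sample, n), prob = w))
  P0 <- moving$vertices[idx, , drop = FALSE]
  # candidate kept fractions for the fractional trimming criterion
  fracs <- seq(0.5, 1 - params$trim, by = 0.025)
  if (!length(fracs)) fracs <- 1 - params$trim
  fixed_fn <- face_normals(fixed)
  moving_vn <- vertex_normals(moving)

  run <- function(Pts, Nts, T0, max_iter) {
    Tcur <- T0
    rms_log <- numeric(0)
    converged <- FALSE
    iter <- 0L
    frmsd_cur <- Inf
    for (iter in seq_len(max_iter)) {
      P <- apply_rigid(Pts, Tcur)
      cs <- closest_on_surface(P, fixed)
      # reject correspondences with incompatible surface orientation:
      # new (cut) surface pairing with old bone surface shows up as a
      # large normal disagreement at any pose
      ndot <- rowSums((Nts %*% t(Tcur$rotation)) * fixed_fn[cs$face, , drop = FALSE])
      ok <- which(ndot > 0.5)
      if (length(ok) < 12L) ok <- seq_len(nrow(Pts))
      keep_ns <- pmax(3L, ceiling(fracs * length(ok)))
      o <- ok[order(cs$distance[ok])]
      cum <- cumsum(cs$distance[o]^2)
      rms_f <- sqrt(cum[keep_ns] / keep_ns)
      frmsd <- (rms_f + 1e-12) / fracs^3
      pick <- which.min(frmsd)
      sel <- o[seq_len(keep_ns[pick])]
      rms <- rms_f[pick]
      frmsd_cur <- frmsd[pick]
      rms_log <- c(rms_log, rms)
      if (iter > 1L && abs(rms_log[iter - 1L] - rms) < params$tol) {
        converged <- TRUE
        break
      }
      Psel <- apply_rigid(Pts[sel, , drop = FALSE], Tcur)
      Qsel <- cs$points[sel, , drop = FALSE]
      Nsel <- fixed_fn[cs$face[sel], , drop = FALSE]
      # two candidate updates: point-to-plane converges fast on smooth,
      # sliding-prone bone but can overstep; Kabsch (point-to-point) is
      # unconditionally stable. Keep whichever fits the surface better.
      cand <- list(kabsch(Pts[sel, , drop = FALSE], Qsel))
      step <- point_to_plane_step(Psel, Qsel, Nsel)
      if (!is.null(step)) cand <- c(cand, list(compose_rigid(step, Tcur)))
      score <- vapply(cand, function(Tc) {
        d2 <- closest_on_surface(apply_rigid(Pts[sel, , drop = FALSE], Tc),
                                 fixed)$distance^2
        sqrt(mean(sort(d2)[seq_len(ceiling(0.9 * length(d2)))]))
      }, numeric(1))
      Tcur <- cand[[which.min(score)]]
    }
    list(transform = Tcur, rms = rms_log[length(rms_log)],
         frmsd = frmsd_cur,
         converged = converged, iterations = iter, rms_log = rms_log)
  }

  # cheap burn-in from every pre-alignment candidate on a point subset,
  # then full refinement of the two most promising; ranking uses the
  # fractional criterion, which does not reward a wrong pose that fits
  # only an aggressively trimmed subset
  N0 <- moving_vn[idx, , drop = FALSE]
  nb <- seq_len(min(250L, nrow(P0)))
  burn <- lapply(starts, function(T0)
    run(P0[nb, , drop = FALSE], N0[nb, , drop = FALSE], T0,
        min(12L, params$max_iter)))
  ord <- order(vapply(burn, `[[`, 0, "frmsd"))
  finals <- lapply(burn[ord[seq_len(min(2L, length(ord)))]], function(b)
    run(P0, N0, b$transform, params$max_iter))
  fin <- finals[[which.min(vapply(finals, `[[`, 0, "frmsd"))]]
  structure(fin[c("transform", "rms", "converged", "iterations", "rms_log")],
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("<icp_result> trimmed RMS %.4f mm after %d iteration(s)%s\n",
              x$rms, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}
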