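test_that("signed plane distance follows the orientation convention", {
  p <- plane3(c(1, 2, 3), c(0, 0, 2))   # normal normalized internally
  expect_equal(signed_plane_distance(p$anchor, p), 0)
  expect_equal(signed_plane_distance(p$anchor + p$normal, p), 1.0)
  expect_equal(signed_plane_distance(p$anchor - 2.5 * p$normal, p), -2.5)
  expect_error(plane3(c(0, 0, 0), c(0, 0, 0)), "degenerate")
  # vectorized over points
  pts <- rbind(p$anchor, p$anchor + 3 * p$normal)
  expect_equal(signed_plane_distance(pts, p), c(0, 3))
})

test_that("mesh-to-plane minimum distance is exact at vertices", {
  p <- plane3(c(0, 0, 0), c(0, 0, 1))
  s <- icosphere(3)
  sph <- tri_mesh(s$vertices + matrix(c(0, 0, 5), nrow(s$vertices), 3,
                                      byrow = TRUE), s$faces)
  # unit sphere centred 5 above the plane: closest vertex ~ 4 (chord gap)
  expect_equal(min_signed_distance_to_plane(sph, p), 4, tolerance = 0.005)
  # straddling sphere: ~ -(r - d)
  sph2 <- tri_mesh(s$vertices * 3 + matrix(c(0, 0, 2), nrow(s$vertices), 3,
                                           byrow = TRUE), s$faces)
  expect_equal(min_signed_distance_to_plane(sph2, p), -1, tolerance = 0.02)
  # a vertex exactly on the plane, rest above
  m <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 1), c(0, 1, 1)), rbind(c(1, 2, 3)))
  expect_equal(min_signed_distance_to_plane(m, p), 0)
  expect_error(min_signed_distance_to_plane(tri_mesh(NULL, NULL), p), "empty")
})

test_that("minimum distance equals a brute-force oracle on random shapes", {
  for (seed in 1:10) {
    blob <- random_blob(seed)
    pl <- with_seed(seed + 100,
                    plane3(stats::rnorm(3, sd = 5), stats::rnorm(3)))
    expect_equal(min_signed_distance_to_plane(blob, pl),
                 brute_min_signed_distance(blob, pl), tolerance = 1e-12)
  }
})

test_that("rigid transforms compose, invert and preserve distances", {
  expect_equal(apply_rigid(c(1, 0, 0),
                           rigid3(rotation_about_axis(c(0, 0, 1), 90))),
               c(0, 1, 0), tolerance = 1e-12)
  Tr <- random_rigid(seed = 4)
  expect_equal(apply_rigid(apply_rigid(c(3, -2, 7), Tr), invert_rigid(Tr)),
               c(3, -2, 7), tolerance = 1e-9)
  m <- random_blob(2)
  m2 <- apply_rigid(m, Tr)
  d1 <- as.matrix(dist(m$vertices[1:40, ]))
  d2 <- as.matrix(dist(m2$vertices[1:40, ]))
  expect_lt(max(abs(d1 - d2)), 1e-9)
  expect_error(rigid3(matrix(1, 3, 3)), "orthonormal")
  expect_error(rigid3(diag(c(1, 1, -1))), "det")
})

test_that("distance computations are invariant under a common rigid motion", {
  blob <- random_blob(5)
  pl <- plane3(c(2, 1, -3), c(1, 2, 2))
  Tr <- random_rigid(seed = 11)
  pl_t <- plane3(apply_rigid(pl$anchor, Tr),
                 as.numeric(Tr$rotation %*% pl$normal))
  expect_equal(min_signed_distance_to_plane(apply_rigid(blob, Tr), pl_t),
               min_signed_distance_to_plane(blob, pl), tolerance = 1e-9)
})

test_that("plane clipping caps, conserves volume and is idempotent", {
  cube <- cube_mesh(size = 30)
  mid <- plane3(c(0, 0, 0), c(0, 0, 1))
  lo <- clip_by_plane(cube, mid, "negative")
  hi <- clip_by_plane(cube, mid, "positive")
  expect_equal(mesh_volume(lo), 13500, tolerance = 1e-6)
  expect_equal(mesh_volume(hi), 13500, tolerance = 1e-6)
  expect_true(is_watertight(lo) && is_watertight(hi))
  expect_lt(max(signed_plane_distance(lo$vertices, mid)), 1e-6)

  # plane missing the mesh entirely
  far <- plane3(c(0, 0, 100), c(0, 0, 1))
  expect_equal(n_vertices(clip_by_plane(cube, far, "positive")), 0)
  expect_equal(mesh_volume(clip_by_plane(cube, far, "negative")),
               mesh_volume(cube))

  # idempotence
  lo2 <- clip_by_plane(lo, mid, "negative")
  expect_equal(mesh_volume(lo2), mesh_volume(lo), tolerance = 1e-9)

  # volume conservation on random watertight shapes, including a shell
  for (seed in 1:6) {
    blob <- random_blob(seed, radius = 12)
    pl <- with_seed(seed + 50, plane3(stats::rnorm(3, sd = 3), stats::rnorm(3)))
    v <- mesh_volume(blob)
    va <- mesh_volume(clip_by_plane(blob, pl, "negative", cap_max_edge = 3))
    vb <- mesh_volume(clip_by_plane(blob, pl, "positive", cap_max_edge = 3))
    expect_equal(va + vb, v, tolerance = 1e-6 * v)
  }
  ph <- small_phantom()
  pl <- plane3(c(8, 0, 0), c(1, 0, 0))   # annular cross-section
  va <- mesh_volume(clip_by_plane(ph$bone, pl, "negative", cap_max_edge = 3))
  vb <- mesh_volume(clip_by_plane(ph$bone, pl, "positive", cap_max_edge = 3))
  expect_equal(va + vb, mesh_volume(ph$bone),
               tolerance = 1e-6 * mesh_volume(ph$bone))
})

test_that("plane sections report loops, area and centroid", {
  cube <- cube_mesh(size = 30)
  sec <- plane_section(cube, plane3(c(0, 0, 0), c(0, 0, 1)))
  expect_equal(sec$area, 900, tolerance = 1e-9)
  expect_equal(sec$centroid, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(sec$max_radius, 15 * sqrt(2), tolerance = 1e-9)
  # shell section has a hole: area = outer - hole
  ph <- small_phantom()
  sec2 <- plane_section(ph$bone, plane3(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(length(sec2$loops), 2L)
  expect_null(plane_section(cube, plane3(c(0, 0, 100), c(0, 0, 1))))
})

test_that("STL and PLY round-trips preserve geometry", {
  tet <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                  rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
  td <- withr::local_tempdir()
  fb <- file.path(td, "tet_bin.stl")
  fa <- file.path(td, "tet_asc.stl")
  fp <- file.path(td, "tet.ply")
  write_mesh(tet, fb)
  write_mesh(tet, fa, ascii = TRUE)
  write_mesh(tet, fp)
  mb <- read_mesh(fb); ma <- read_mesh(fa); mp <- read_mesh(fp)
  for (m in list(mb, ma, mp)) {
    expect_equal(n_faces(m), 4L)
    expect_true(is_watertight(m))
    expect_equal(mesh_volume(m), mesh_volume(tet), tolerance = 1e-6)
    expect_equal(m$vertices[order(m$vertices[, 1], m$vertices[, 2], m$vertices[, 3]), ],
                 tet$vertices[order(tet$vertices[, 1], tet$vertices[, 2], tet$vertices[, 3]), ],
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  # larger welded round-trip keeps exact connectivity counts
  blob <- random_blob(3, subdiv = 2)
  write_mesh(blob, fb)
  rb <- read_mesh(fb)
  expect_equal(n_vertices(rb), n_vertices(blob))
  expect_equal(mesh_volume(rb), mesh_volume(blob), tolerance = 1e-4)

  bad <- file.path(td, "empty.stl")
  file.create(bad)
  expect_error(read_mesh(bad), "unreadable|STL")
  expect_error(read_mesh(fb, units = "cm"), "millimetre")
  expect_error(read_mesh(file.path(td, "absent.stl")), "not found")
})

test_that("plane JSON and transform JSON round-trip", {
  p <- plane3(c(1.5, -2, 3), c(1, 1, 0))
  p2 <- plane_from_list(plane_to_list(p))
  expect_equal(p2$anchor, p$anchor)
  expect_equal(p2$normal, p$normal)
  Tr <- random_rigid(seed = 9)
  f <- withr::local_tempfile(fileext = ".json")
  write_rigid_json(Tr, f, extra = list(rms_mm = 0.12))
  Tr2 <- read_rigid_json(f)
  expect_equal(Tr2$rotation, Tr$rotation, tolerance = 1e-12)
  expect_equal(Tr2$translation, Tr$translation, tolerance = 1e-12)
  expect_equal(attr(Tr2, "meta")$rms_mm, 0.12)
})
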