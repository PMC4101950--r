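test_that("tangent planes sit at the requested margin", {
  s <- icosphere(3)                       # unit sphere at the origin
  p <- tangent_plane_at_margin(s, c(0, 0, 1), 6)
  expect_equal(p$normal, c(0, 0, 1))
  expect_equal(p$anchor[3], -7, tolerance = 1e-9)
  expect_equal(planned_margin(p, s), 6, tolerance = 1e-12)
  p0 <- tangent_plane_at_margin(s, c(0, 0, 1), 0)
  expect_equal(planned_margin(p0, s), 0, tolerance = 1e-12)
  expect_identical(tangent_plane_at_margin(s, c(1, 2, 3), 4),
                   tangent_plane_at_margin(s, c(1, 2, 3), 4))
  expect_error(tangent_plane_at_margin(s, c(0, 0, 0), 5), "degenerate")
})

test_that("tangent-then-measure is the identity on the margin", {
  ph <- small_phantom()
  for (seed in 1:8) {
    dir <- with_seed(seed, random_unit_vector())
    m <- with_seed(seed + 20, stats::runif(1, 0, 15))
    p <- tangent_plane_at_margin(ph$tumor, dir, m)
    expect_equal(planned_margin(p, ph$tumor), m, tolerance = 1e-6)
    expect_equal(planned_margin(p, ph$tumor),
                 brute_min_signed_distance(ph$tumor, p), tolerance = 1e-12)
  }
  centre_plane <- plane3(c(25, 8, 0), c(0, 0, 1))  # through the tumor centre
  expect_lt(planned_margin(centre_plane, ph$tumor), 0)
})

test_that("shifting a plane toward the tumor reduces the margin exactly", {
  ph <- small_phantom()
  p <- tangent_plane_at_margin(ph$tumor, c(1, 0, 0), 10)
  for (delta in c(0.5, 2, 7)) {
    expect_equal(planned_margin(offset_plane(p, delta), ph$tumor), 10 - delta,
                 tolerance = 1e-9)
  }
})

test_that("strategies hold 1 to 6 validated planes", {
  ph <- small_phantom()
  mk <- function(margin, label, dir = c(1, 0, 0))
    target_plane_spec(tangent_plane_at_margin(ph$tumor, dir, margin),
                      desired_safe_margin = margin, label = label)
  expect_equal(length(build_strategy(list(mk(10, "a")))), 1L)
  st4 <- build_strategy(list(mk(10, "a"), mk(12, "b", c(0, 1, 0)),
                             mk(5, "c", c(0, 0, 1)), mk(8, "d", c(-1, 0, 0))),
                        tumor = ph$tumor)
  expect_equal(length(st4), 4L)
  expect_error(build_strategy(list()), "1 to 6")
  expect_error(build_strategy(replicate(7, mk(10, "x"), simplify = FALSE)),
               "1 to 6|unique")
  specs7 <- lapply(1:7, function(i) mk(10, paste0("p", i)))
  expect_error(build_strategy(specs7), "1 to 6")
  # a plane closer than the desired margin is unsafe
  unsafe <- target_plane_spec(offset_plane(tangent_plane_at_margin(
    ph$tumor, c(1, 0, 0), 10), 4), desired_safe_margin = 10, label = "bad")
  expect_error(build_strategy(list(unsafe), tumor = ph$tumor), "bad")
  expect_warning(mk(2, "tight"), "below 3 mm")
  # margin-free plane is allowed
  free <- target_plane_spec(tangent_plane_at_margin(ph$tumor, c(0, 1, 0), 5),
                            desired_safe_margin = NA, label = "free")
  expect_equal(length(build_strategy(list(free), tumor = ph$tumor)), 1L)
})

test_that("cutting depth measures the deepest bone along the direction line", {
  cube <- cube_mesh(size = 30)
  pl <- plane3(c(0, 0, 0), c(0, 0, 1))
  edge <- c(-15, 0, 0)
  expect_equal(cutting_depth(cube, pl, edge, c(1, 0, 0)), 30, tolerance = 1e-9)
  expect_equal(cutting_depth(cube, pl, edge, c(-1, 0, 0)), 0)
  expect_error(cutting_depth(cube, pl, edge, c(0, 0, 1)), "lie in")

  # ellipsoid cross-section against a dense sampling oracle
  ell <- ellipsoid_mesh(c(0, 0, 0), c(20, 12, 9), 4)
  pl2 <- plane3(c(0, 0, 2), c(0, 0, 1))
  edge2 <- c(-25, 1, 2)
  got <- cutting_depth(ell, pl2, edge2, c(1, 0, 0))
  sec <- plane_section(ell, pl2)
  loop2d <- sec$loops[[1]][, 1:2]
  ts <- seq(0, 50, by = 0.002)
  inside <- vapply(ts, function(t) {
    pt <- edge2[1:2] + t * c(1, 0)
    # even-odd test against the section polygon
    n <- nrow(loop2d); cross <- FALSE; j <- n
    for (i in seq_len(n)) {
      if ((loop2d[i, 2] > pt[2]) != (loop2d[j, 2] > pt[2]) &&
          pt[1] < (loop2d[j, 1] - loop2d[i, 1]) * (pt[2] - loop2d[i, 2]) /
            (loop2d[j, 2] - loop2d[i, 2]) + loop2d[i, 1])
        cross <- !cross
      j <- i
    }
    cross
  }, logical(1))
  oracle <- max(ts[inside])
  expect_equal(got, oracle, tolerance = 0.01)
})

test_that("cutting depth is invariant under joint rigid motion", {
  cube <- cube_mesh(size = 30)
  pl <- plane3(c(0, 0, 0), c(0, 0, 1))
  edge <- c(-15, 2, 0)
  Tr <- random_rigid(seed = 31)
  d0 <- cutting_depth(cube, pl, edge, c(1, 0, 0))
  d1 <- cutting_depth(apply_rigid(cube, Tr),
                      plane3(apply_rigid(pl$anchor, Tr),
                             as.numeric(Tr$rotation %*% pl$normal)),
                      apply_rigid(edge, Tr),
                      as.numeric(Tr$rotation %*% c(1, 0, 0)))
  expect_equal(d1, d0, tolerance = 1e-6)
})

test_that("strategy JSON round-trips, including margin-free planes", {
  ph <- small_phantom()
  s1 <- target_plane_spec(tangent_plane_at_margin(ph$tumor, c(1, 0, 0), 10),
                          desired_safe_margin = 10, label = "iliac")
  s2 <- target_plane_spec(tangent_plane_at_margin(ph$tumor, c(0, 1, 0), 5),
                          desired_safe_margin = NA, label = "extra-articular")
  st <- build_strategy(list(s1, s2), case_id = "case-1")
  f <- withr::local_tempfile(fileext = ".json")
  write_strategy_json(st, f)
  st2 <- read_strategy_json(f)
  expect_equal(length(st2), 2L)
  sp <- strategy_specs(st2)
  expect_equal(sp[[1]]$desired_safe_margin, 10)
  expect_true(is.na(sp[[2]]$desired_safe_margin))
  expect_equal(sp[[1]]$plane$anchor, s1$plane$anchor, tolerance = 1e-12)
  expect_equal(sp[[2]]$label, "extra-articular")
})
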