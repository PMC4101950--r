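test_that("phantoms are watertight, deterministic and contain the tumor", {
  a <- make_phantom(phantom_params(edge_length = 5, seed = 3))
  b <- make_phantom(phantom_params(edge_length = 5, seed = 3))
  expect_identical(a$bone$vertices, b$bone$vertices)
  expect_identical(a$tumor$vertices, b$tumor$vertices)
  expect_true(is_watertight(a$bone))
  expect_true(is_watertight(a$tumor))
  # tumor strictly inside the outer bone surface
  q <- rowSums((a$tumor$vertices / matrix(c(60, 40, 30),
                                          nrow(a$tumor$vertices), 3,
                                          byrow = TRUE))^2)
  expect_true(all(q < 1))
  expect_error(make_phantom(phantom_params(tumor_semi_axes = c(35, 35, 35))),
               "containable")
})

test_that("zero noise and zero kerf reproduce the target planes exactly", {
  ph <- small_phantom()
  st <- default_strategy(ph$tumor, margins = c(10, 12))
  zero <- data.frame(delta_mm = c(0, 0), tilt_deg = 0, axis_deg = 0)
  sim <- simulate_resection(ph$bone, ph$tumor, st, noise = cut_noise(kerf = 0),
                            perturbations = zero, carve = FALSE)
  for (j in 1:2) {
    tp <- strategy_specs(st)[[j]]$plane
    ap <- sim$achieved_planes[[j]]
    expect_equal(sum(ap$normal * tp$normal), 1, tolerance = 1e-12)
    expect_lt(abs(signed_plane_distance(ap$anchor, tp)), 1e-12)
  }
})

test_that("kerf places the remaining-bone cut face beyond the plane", {
  ph <- small_phantom()
  st <- default_strategy(ph$tumor, margins = 10)
  zero <- data.frame(delta_mm = 0, tilt_deg = 0, axis_deg = 0)
  tp <- strategy_specs(st)[[1]]$plane
  for (k in c(0.9, 1.4)) {
    sim <- simulate_resection(ph$bone, ph$tumor, st,
                              noise = cut_noise(kerf = k),
                              perturbations = zero)
    d <- signed_plane_distance(sim$remaining_bone$vertices, tp)
    expect_lt(max(d), -k + 1e-6)           # nothing beyond the kerf face
    expect_equal(max(d), -k, tolerance = 1e-6)  # the face sits exactly there
  }
})

test_that("a plane missing the bone is rejected by name", {
  ph <- small_phantom()
  sp <- target_plane_spec(plane3(c(0, 0, 200), c(0, 0, -1)),
                          desired_safe_margin = 10, label = "off-bone")
  st <- build_strategy(list(sp))
  expect_error(simulate_resection(ph$bone, ph$tumor, st), "off-bone")
})

test_that("scan noise applies the transform then seeded jitter", {
  ph <- small_phantom()
  m <- ph$tumor
  expect_identical(apply_scan_noise(m, rigid3(), 0, seed = 1)$vertices,
                   m$vertices)
  Tr <- random_rigid(seed = 21)
  expect_equal(apply_scan_noise(m, Tr, 0, seed = 1)$vertices,
               apply_rigid(m, Tr)$vertices)
  a <- apply_scan_noise(m, Tr, 0.2, seed = 5)
  b <- apply_scan_noise(m, Tr, 0.2, seed = 5)
  expect_identical(a$vertices, b$vertices)
  # RMS displacement of i.i.d. jitter ~ sd * sqrt(3) (chi distribution)
  big <- icosphere(5)          # > 10^4 vertices
  j <- apply_scan_noise(big, rigid3(), 0.2, seed = 2)
  rms <- sqrt(mean(rowSums((j$vertices - big$vertices)^2)))
  expect_equal(rms, 0.2 * sqrt(3), tolerance = 0.1 * 0.2 * sqrt(3))
})

test_that("translation noise SD is recovered from simulated planes", {
  ph <- small_phantom()
  st <- default_strategy(ph$tumor, margins = c(3, 5, 8, 10, 12, 15))
  offs <- numeric(0)
  for (s in 1:34) {
    sim <- simulate_resection(ph$bone, ph$tumor, st,
                              noise = cut_noise(sigma_t = 1, sigma_theta = 0,
                                                kerf = 0, seed = s),
                              carve = FALSE)
    for (j in 1:6) {
      tp <- strategy_specs(st)[[j]]$plane
      ap <- sim$achieved_planes[[j]]
      offs <- c(offs, signed_plane_distance(ap$anchor, tp))
    }
  }
  expect_gte(length(offs), 200)
  expect_equal(sd(offs), 1.0, tolerance = 0.15)
})

test_that("increasing kerf shifts the cut face monotonically", {
  ph <- small_phantom()
  st <- default_strategy(ph$tumor, margins = 10)
  zero <- data.frame(delta_mm = 0, tilt_deg = 0, axis_deg = 0)
  tp <- strategy_specs(st)[[1]]$plane
  faces <- vapply(c(0, 0.5, 1.0, 1.5), function(k) {
    sim <- simulate_resection(ph$bone, ph$tumor, st,
                              noise = cut_noise(kerf = k),
                              perturbations = zero)
    max(signed_plane_distance(sim$remaining_bone$vertices, tp))
  }, numeric(1))
  expect_equal(diff(faces), rep(-0.5, 3), tolerance = 1e-6)
})

test_that("resection conserves material: remaining + specimen = bone", {
  ph <- small_phantom()
  st <- default_strategy(ph$tumor, margins = c(3, 8, 12),
                         directions = rbind(c(1, 0, 0), c(0, 1, 0),
                                            c(0, 0, 1)))
  zero <- data.frame(delta_mm = rep(0, 3), tilt_deg = 0, axis_deg = 0)
  sim <- simulate_resection(ph$bone, ph$tumor, st, noise = cut_noise(kerf = 0),
                            perturbations = zero)
  vb <- mesh_volume(ph$bone)
  expect_equal(mesh_volume(sim$remaining_bone) + mesh_volume(sim$specimen),
               vb, tolerance = 1e-6 * vb)
})
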