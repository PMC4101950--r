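test_that("total-least-squares plane fit is exact and well oriented", {
  pts <- rbind(c(0, 0, 3), c(1, 0, 3), c(0, 1, 3), c(1, 1, 3))
  ft <- fit_plane(pts, orient_toward = c(0, 0, 1))
  expect_equal(abs(ft$plane$normal[3]), 1, tolerance = 1e-12)
  expect_equal(ft$plane$normal[3], 1)      # oriented as requested
  expect_equal(ft$plane$anchor[3], 3)
  expect_equal(ft$rms, 0, tolerance = 1e-12)
  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               "collinear|degenerate")
  # noisy samples: normal recovered within 1 degree at n = 500
  pl <- plane3(c(1, 2, 3), c(1, 1, 2))
  E <- cbind(c(1, -1, 0) / sqrt(2), c(1, 1, -1) / sqrt(3))
  noisy <- with_seed(12, {
    uv <- matrix(stats::runif(1000, -20, 20), ncol = 2)
    base <- matrix(pl$anchor, 500, 3, byrow = TRUE) + uv %*% t(E)
    base + matrix(stats::rnorm(1500, 0, 0.1), 500, 3)
  })
  ft2 <- fit_plane(noisy, orient_toward = pl$normal)
  ang <- acos(min(1, sum(ft2$plane$normal * pl$normal))) * 180 / pi
  expect_lt(ang, 1)
})

eval_case <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ph <- make_phantom(phantom_params(edge_length = 5))
    st <- default_strategy(ph$tumor, margins = c(10, 12))
    zero <- data.frame(delta_mm = c(0, 0), tilt_deg = 0, axis_deg = 0)
    sim <- simulate_resection(ph$bone, ph$tumor, st,
                              noise = cut_noise(kerf = 0),
                              perturbations = zero)
    cache <<- list(ph = ph, st = st, sim = sim)
    cache
  }
})

test_that("cut surfaces are extracted and matched to their targets", {
  cs <- eval_case()
  cuts <- extract_cut_surfaces(cs$sim$remaining_bone, cs$ph$bone, cs$st)
  expect_length(cuts, 2)
  for (j in 1:2) {
    expect_false(is.null(cuts[[j]]))
    tp <- strategy_specs(cs$st)[[j]]$plane
    expect_equal(abs(sum(cuts[[j]]$plane$normal * tp$normal)), 1,
                 tolerance = 1e-9)
    expect_lt(abs(signed_plane_distance(cuts[[j]]$plane$anchor, tp)), 1e-6)
    expect_gt(cuts[[j]]$n_points, 25)
  }
  # a novelty threshold larger than the bone finds nothing; targets are
  # reported missing, not as an error
  none <- extract_cut_surfaces(cs$sim$remaining_bone, cs$ph$bone, cs$st,
                               novelty_threshold = 500)
  expect_true(all(vapply(none, is.null, logical(1))))
})

test_that("surgical margin matches the brute-force vertex minimum", {
  cs <- eval_case()
  cuts <- extract_cut_surfaces(cs$sim$remaining_bone, cs$ph$bone, cs$st)
  sm <- surgical_margin(cuts[[1]], cs$ph$tumor)
  expect_equal(sm, brute_min_signed_distance(cs$ph$tumor, cuts[[1]]$plane),
               tolerance = 1e-12)
  expect_equal(sm, 10, tolerance = 1e-6)
  # tangent plane gives a zero margin
  tangent <- tangent_plane_at_margin(cs$ph$tumor, c(1, 0, 0), 0)
  expect_equal(surgical_margin(tangent, cs$ph$tumor), 0, tolerance = 1e-9)
})

test_that("ESM is the difference between achieved and desired margins", {
  expect_equal(error_in_safe_margin(6.6, 10), -3.4)
  expect_equal(error_in_safe_margin(5.7, 5), 0.7)
  expect_equal(error_in_safe_margin(8, 8), 0)
  expect_true(is.na(error_in_safe_margin(5, NA)))
})

test_that("location accuracy is the max distance along the target normal", {
  tp <- plane3(c(0, 0, 0), c(0, 0, 1))
  E2 <- cbind(c(1, 0, 0), c(0, 1, 0))
  disk <- with_seed(3, {
    th <- stats::runif(400, 0, 2 * pi); r <- sqrt(stats::runif(400)) * 30
    cbind(r * cos(th), r * sin(th), 0)
  })
  expect_equal(location_accuracy(disk, tp), 0)
  off <- disk; off[, 3] <- 2.5
  expect_equal(location_accuracy(off, tp), 2.5)
  # tilt about an axis through the footprint centroid: L = rho sin(theta)
  th <- 2 * pi / 180
  R <- rotation_about_axis(c(1, 0, 0), 2)
  tilted <- disk %*% t(R)
  rho <- max(abs(disk[, 2]))               # distance from the x tilt axis
  expect_equal(location_accuracy(tilted, tp), rho * sin(th),
               tolerance = 0.01 * rho * sin(th))
  expect_error(location_accuracy(matrix(numeric(0), 0, 3), tp), "points")
})

test_that("L is rigid-invariant and bounded below by the mean offset", {
  tp <- plane3(c(1, -2, 5), c(1, 2, 1))
  pts <- with_seed(9, matrix(stats::rnorm(300, sd = 10), ncol = 3))
  Tr <- random_rigid(seed = 14)
  tp_t <- plane3(apply_rigid(tp$anchor, Tr),
                 as.numeric(Tr$rotation %*% tp$normal))
  expect_equal(location_accuracy(apply_rigid(pts, Tr), tp_t),
               location_accuracy(pts, tp), tolerance = 1e-9)
  expect_gte(location_accuracy(pts, tp),
             abs(mean(signed_plane_distance(pts, tp))))
  # equality iff the cut is a pure parallel translation
  flat <- pts - outer(signed_plane_distance(pts, tp), tp$normal)
  shifted <- flat + matrix(1.7 * tp$normal, nrow(flat), 3, byrow = TRUE)
  expect_equal(location_accuracy(shifted, tp),
               abs(mean(signed_plane_distance(shifted, tp))),
               tolerance = 1e-9)
})

test_that("kerf correction subtracts the blade only on the tumor side", {
  expect_equal(kerf_correct(3.0, 0.9, TRUE), 2.1)
  expect_equal(kerf_correct(3.0, 0.9, FALSE), 3.0)
  expect_equal(kerf_correct(0.5, 0.9, TRUE), 0)
  expect_error(kerf_correct(1, -0.1, TRUE), ">= 0")
})

test_that("margin classes follow the UICC rule with its boundaries", {
  expect_equal(classify_margin(5.2), "R0")
  expect_equal(classify_margin(0.5), "R1")
  expect_equal(classify_margin(-1.0), "intralesional")
  expect_equal(classify_margin(1.0), "R1")      # boundary: SM = 1 is not > 1
  expect_equal(classify_margin(0.0), "R1")      # boundary: 0 <= SM <= 1
  expect_equal(classify_margin(1.0 + 1e-9), "R0")
  expect_equal(classify_margin(NA), "n/a")
  expect_equal(classify_margin(c(2, 0.3, -2)),
               c("R0", "R1", "intralesional"))
})

test_that("case evaluation produces coherent records", {
  cs <- eval_case()
  rec <- evaluate_case(cs$ph$bone, cs$ph$tumor, cs$st, cs$sim$remaining_bone,
                       registration = rigid3())
  expect_s3_class(rec, "evaluation_records")
  expect_equal(nrow(rec), 2L)
  expect_true(all(rec$matched))
  expect_lt(max(abs(rec$esm_mm)), 0.05)
  expect_lt(max(rec$l_mm), 0.05)
  # the record invariant ESM = SM - d holds exactly
  expect_identical(rec$esm_mm, rec$sm_mm - rec$desired_margin_mm)
  expect_true(all(rec$margin_class == "R0"))
})

test_that("margin-free planes report location accuracy only", {
  ph <- make_phantom(phantom_params(edge_length = 5))
  s1 <- target_plane_spec(tangent_plane_at_margin(ph$tumor, c(1, 0, 0), 10),
                          desired_safe_margin = 10, label = "margined")
  s2 <- target_plane_spec(tangent_plane_at_margin(ph$tumor, c(0, 1, 0), 8),
                          desired_safe_margin = NA, label = "free")
  st <- build_strategy(list(s1, s2), tumor = ph$tumor)
  zero <- data.frame(delta_mm = c(0, 0), tilt_deg = 0, axis_deg = 0)
  sim <- simulate_resection(ph$bone, ph$tumor, st, noise = cut_noise(kerf = 0),
                            perturbations = zero)
  rec <- evaluate_case(ph$bone, ph$tumor, st, sim$remaining_bone,
                       registration = rigid3())
  free <- rec[rec$plane_label == "free", ]
  expect_true(is.na(free$sm_mm) && is.na(free$esm_mm))
  expect_equal(free$margin_class, "n/a")
  expect_lt(free$l_mm, 0.05)
})

test_that("a seeded noisy case recovers ground-truth SM and L closely", {
  ph <- make_phantom(phantom_params(edge_length = 5))
  st <- default_strategy(ph$tumor, margins = c(10, 12))
  sim <- simulate_resection(ph$bone, ph$tumor, st,
                            noise = cut_noise(sigma_t = 1, sigma_theta = 1.5,
                                              kerf = 0, seed = 13))
  rec <- evaluate_case(ph$bone, ph$tumor, st, sim$remaining_bone,
                       registration = rigid3())
  sm_true <- vapply(sim$achieved_planes, function(p)
    min_signed_distance_to_plane(ph$tumor, p), numeric(1))
  expect_lt(max(abs(rec$sm_mm - sm_true)), 0.2)
})
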