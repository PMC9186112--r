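test_that("sphericity matches closed forms and is scale invariant", {
  # definitional: a perfect sphere
  expect_equal(sphericity(4 * pi / 3, 4 * pi), 1, tolerance = 1e-12)
  # unit cube
  expect_equal(sphericity(1, 6), (pi / 6)^(1 / 3), tolerance = 1e-12)
  # cylinder with h = 2r: V = 2 pi r^3, A = 6 pi r^2
  expect_equal(sphericity(2 * pi, 6 * pi), 12^(2 / 3) / 6, tolerance = 1e-12)
  expect_error(sphericity(0, 1), "positive")

  set.seed(2)
  for (i in 1:20) {
    V <- stats::runif(1, 0.01, 5); A <- stats::runif(1, 1, 20)
    s <- stats::runif(1, 0.01, 100)
    expect_equal(sphericity(V * s^3, A * s^2), sphericity(V, A),
                 tolerance = 1e-9)
  }
})

test_that("mesh sphericity respects the isoperimetric bound", {
  set.seed(3)
  for (i in 1:6) {
    s <- make_spine(head_radii = stats::runif(3, 0.3, 0.7),
                    neck_length = stats::runif(1, 0.3, 1),
                    neck_radius = 0.12, seed = i, mesh_resolution = 1)
    m <- s$spine$mesh
    expect_lte(sphericity(abs(signed_volume(m)), surface_area(m)), 1 + 1e-6)
  }
  cube <- cube_mesh()
  expect_equal(sphericity(signed_volume(cube), surface_area(cube)),
               (pi / 6)^(1 / 3), tolerance = 1e-12)
})

test_that("head volume matches the analytic primitives", {
  s <- make_spine(head_radii = c(0.5, 0.5, 0.5), seed = 1)
  labs <- separate(s$spine)
  expect_equal(head_volume(s$spine, labs), 4 / 3 * pi * 0.125,
               tolerance = 0.02)
  e <- make_spine(head_radii = c(0.5, 0.4, 0.3), neck_radius = 0.12,
                  seed = 2)
  labs_e <- separate(e$spine)
  expect_equal(head_volume(e$spine, labs_e), 4 / 3 * pi * 0.5 * 0.4 * 0.3,
               tolerance = 0.025)
  expect_error(head_volume(s$spine, list(separable = FALSE)),
               "not separable")
})

test_that("neck length is an arc length, not a chord", {
  s <- make_spine(neck_length = 0.6, seed = 3, mesh_resolution = 1)
  labs <- separate(s$spine)
  expect_equal(as.numeric(neck_length(s$spine, labs)), 0.6, tolerance = 0.1)

  # 90-degree bend: arc 0.6, chord 2*R*sin(pi/4) = 0.54; the measurement
  # must track the arc
  b <- make_spine(neck_length = 0.6, neck_curvature = 90, seed = 4,
                  mesh_resolution = 2)
  labs_b <- separate(b$spine)
  nl <- as.numeric(neck_length(b$spine, labs_b))
  expect_equal(nl, 0.6, tolerance = 0.1)
})

test_that("neck diameter tracks the tube radius and obeys policy", {
  s <- spineA()
  labs <- spineA_sep()
  d <- neck_diameter(s$spine, labs)
  expect_equal(as.numeric(d), 300, tolerance = 0.1 * 300)
  expect_false(attr(d, "sub_resolution"))

  thin <- make_spine(neck_radius = 0.08, seed = 5, mesh_resolution = 1)
  labs_t <- separate(thin$spine)
  dt <- neck_diameter(thin$spine, labs_t)
  thick <- make_spine(neck_radius = 0.2, seed = 5, mesh_resolution = 1)
  labs_k <- separate(thick$spine)
  dk <- neck_diameter(thick$spine, labs_k)
  expect_lt(as.numeric(dt), as.numeric(dk))  # monotone in true radius
  expect_true(attr(dt, "sub_resolution"))    # 160 nm < 200 nm proxy

  expect_error(neck_diameter(s$spine, labs, repaired = TRUE),
               "not measured on repaired")
})

test_that("spine length reaches the tip along the skeleton", {
  s <- spineA()  # head r=0.5 + neck 0.6: total ~1.6
  sk <- spineA_sep()$skeleton
  expect_equal(as.numeric(spine_length(s$spine, sk)), 1.6,
               tolerance = 0.15 * 1.6)

  # bare sphere with the insertion point on its surface: length = diameter
  sph <- sphere_mesh(0.5, c(0, 0, 0.5), res = 1)
  spsph <- spine_mesh(sph, c(0, 0, 0), spine_id = "sph")
  sk2 <- skeletonize(sph)
  len <- spine_length(spsph, sk2)
  expect_true(isTRUE(attr(len, "flagged")))
  expect_equal(as.numeric(len), 1.0, tolerance = 0.1)

  # homogeneity under uniform scaling
  s2 <- s$spine
  s2$mesh$vertices <- 2 * s2$mesh$vertices
  sk3 <- skeletonize(s2$mesh)
  sk3 <- spinemorph:::augment_skeleton(sk3, s2$insertion_point)
  expect_equal(as.numeric(spine_length(s2, sk3)),
               2 * as.numeric(spine_length(s$spine,
                                           spinemorph:::augment_skeleton(
                                             skeletonize(s$spine$mesh),
                                             s$spine$insertion_point))),
               tolerance = 0.05)
})

test_that("spine volume is additive over primitives and index-invariant", {
  s <- spineA()
  sv <- spine_volume(s$spine)
  neck_cyl <- pi * 0.15^2 * 0.6
  expect_equal(sv, s$truth$head_volume + neck_cyl, tolerance = 0.05)

  cube <- cube_mesh()
  expect_equal(spine_volume(spine_mesh(cube, c(0, 0, 0))), 1,
               tolerance = 1e-9)

  set.seed(4)
  pm <- sample(nrow(cube$vertices))
  inv <- integer(length(pm)); inv[pm] <- seq_along(pm)
  cube2 <- tri_mesh(cube$vertices[pm, ], matrix(inv[cube$faces], ncol = 3))
  expect_equal(spine_volume(spine_mesh(cube2, c(0, 0, 0))), 1,
               tolerance = 1e-9)
})

test_that("measure_spine assembles a consistent record", {
  rec <- measure_spine(spineA()$spine)
  expect_equal(rec$group, "A")
  expect_false(rec$repaired)
  expect_true(is.finite(rec$neck_diameter_nm))
  expect_gt(rec$sphericity, 0.8)
  expect_lte(rec$head_volume_um3 + pi * 0.15^2 * 0.6,
             rec$spine_volume_um3 * 1.05)

  sB <- make_spine(target_group = "B", seed = 13, mesh_resolution = 1)
  recB <- measure_spine(sB$spine)
  expect_equal(recB$group, "B")
  expect_true(is.na(recB$neck_length_um))
  expect_true(is.na(recB$head_volume_um3))
  expect_true(is.finite(recB$spine_volume_um3))
})
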