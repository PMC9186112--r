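test_that("pre-segmentation classification follows the gap and count rules", {
  sC <- make_spine(target_group = "C", neck_length = 0.6, seed = 1,
                   mesh_resolution = 1)
  expect_equal(classify_pre_segmentation(sC$spine), "C")

  sA <- spineA()  # nearest vertex at the insertion point itself
  expect_equal(classify_pre_segmentation(sA$spine), "pending")

  sD <- make_spine(target_group = "D", seed = 2, mesh_resolution = 1)
  expect_equal(classify_pre_segmentation(sD$spine), "D")

  sE <- make_spine(target_group = "E", seed = 3, mesh_resolution = 1)
  expect_equal(classify_pre_segmentation(sE$spine), "E")
  expect_gte(count_components(sE$spine$mesh), 3)
})

test_that("extend_neck adds a gap-length cylinder without touching the head", {
  s <- make_spine(target_group = "C", neck_length = 0.6, seed = 4,
                  mesh_resolution = 1)
  nv0 <- nrow(s$spine$mesh$vertices)
  rr <- extend_neck(s$spine, repair_params(cylinder_radius = 0.17))
  expect_equal(count_components(rr$mesh), 1)
  expect_equal(rr$bridge_length, 0.6, tolerance = 1e-6)
  expect_equal(rr$operations_applied, "neck_extension")
  # original geometry untouched: prefix of vertices and faces identical
  expect_identical(rr$mesh$vertices[seq_len(nv0), ], s$spine$mesh$vertices)
  expect_identical(rr$mesh$faces[seq_len(nrow(s$spine$mesh$faces)), ],
                   s$spine$mesh$faces)
  # added faces disjoint from originals
  expect_gt(min(rr$added_face_ids), nrow(s$spine$mesh$faces))

  # precondition: group A/B spine has no gap
  expect_error(extend_neck(spineA()$spine), "threshold")
})

test_that("repair radius does not change the measured neck length", {
  s <- make_spine(target_group = "C", neck_length = 0.6, seed = 5,
                  mesh_resolution = 1)
  l14 <- measure_spine(repair(s$spine, repair_params(cylinder_radius = 0.14))$spine,
                       group = "C", repaired = TRUE)$neck_length_um
  l17 <- measure_spine(repair(s$spine, repair_params(cylinder_radius = 0.17))$spine,
                       group = "C", repaired = TRUE)$neck_length_um
  expect_equal(l14, l17, tolerance = 0.02)
  expect_equal(l14, 0.6, tolerance = 0.1)
})

test_that("bridge_components joins the mutually closest vertex pair", {
  # two spheres at a known offset: closest pair must be the facing poles
  m1 <- sphere_mesh(0.3, c(0, 0, 0.3), res = 1)
  m2 <- sphere_mesh(0.3, c(0, 0, 1.6), res = 1)
  both <- spinemorph:::merge_meshes(m1, m2)
  sp <- spine_mesh(both, c(0, 0, 0), spine_id = "twosph")
  rr <- bridge_components(sp, repair_params())
  expect_equal(count_components(rr$mesh), 1)
  # brute-force oracle for the closest pair distance
  comp <- mesh_components(both)
  vc <- integer(nrow(both$vertices))
  for (k in 1:2) vc[unique(as.vector(both$faces[comp == k, ]))] <- k
  dmin <- min(as.matrix(stats::dist(both$vertices))[vc == 1, vc == 2])
  expect_equal(rr$bridge_length, dmin, tolerance = 1e-9)
  # facing poles: center distance 1.3 minus the two radii
  expect_equal(dmin, 0.7, tolerance = 0.02)

  expect_error(bridge_components(spineA()$spine), "two components")
})

test_that("repair dispatches, chains operations, and rejects group E", {
  sC <- make_spine(target_group = "C", neck_length = 0.5, seed = 6,
                   mesh_resolution = 1)
  expect_equal(repair(sC$spine)$operations_applied, "neck_extension")

  sD <- make_spine(target_group = "D", seed = 7, mesh_resolution = 1)
  expect_equal(repair(sD$spine)$operations_applied, "component_bridge")

  # a D whose fragment floats away from the insertion point: bridge then
  # extend
  sD2 <- make_spine(target_group = "D", seed = 8, mesh_resolution = 1)
  m <- sD2$spine$mesh
  m$vertices[, 3] <- m$vertices[, 3] + 0.35  # lift everything off the anchor
  spD2 <- sD2$spine
  spD2$mesh <- m
  rr <- repair(spD2)
  expect_setequal(rr$operations_applied,
                  c("component_bridge", "neck_extension"))
  expect_equal(count_components(rr$mesh), 1)

  sE <- make_spine(target_group = "E", seed = 9, mesh_resolution = 1)
  expect_error(repair(sE$spine), class = "spinemorph_discarded")
  expect_error(repair(spineA()$spine), "nothing to repair")
})

test_that("head volume is invariant under repair (per fixture)", {
  sA <- make_spine(seed = 10, mesh_resolution = 1)
  hvA <- head_volume(sA$spine, separate(sA$spine))
  sC <- make_spine(target_group = "C", neck_length = 0.6, seed = 10,
                   mesh_resolution = 1)
  rc <- repair(sC$spine)
  hvC <- head_volume(rc$spine, separate(rc$spine))
  expect_equal(hvC, hvA, tolerance = 0.02)
})
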