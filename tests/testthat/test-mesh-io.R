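test_that("OBJ loading scales units and preserves components", {
  f1 <- withr::local_tempfile(fileext = ".obj")
  writeLines(tetra_obj_lines(), f1)
  m <- load_spine_mesh(f1, unit_scale = 1)
  expect_equal(nrow(m$faces), 4)
  expect_equal(mesh_component_count(m), 1)

  m2 <- load_spine_mesh(f1, unit_scale = 0.001)
  expect_equal(m2$vertices, m$vertices * 0.001)

  f2 <- withr::local_tempfile(fileext = ".obj")
  shifted <- tetra_obj_lines(offset = c(5, 0, 0))
  writeLines(c(tetra_obj_lines(),
               shifted[1:4],
               "f 5 7 6", "f 5 6 8", "f 6 7 8", "f 5 8 7"), f2)
  m3 <- load_spine_mesh(f2)
  expect_equal(mesh_component_count(m3), 2)

  expect_error(load_spine_mesh(f1, unit_scale = -1), "positive")
  expect_error(load_spine_mesh(tempfile(fileext = ".obj")), "cannot read")
  f3 <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0"), f3)
  expect_error(load_spine_mesh(f3), "empty mesh")
})

test_that("ASCII PLY loads and binary PLY is rejected", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 4", "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "3 0 2 1", "3 0 1 3", "3 1 2 3", "3 0 3 2"), f)
  m <- load_spine_mesh(f)
  expect_equal(nrow(m$faces), 4)
  expect_true(is_watertight(m))

  fb <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format binary_little_endian 1.0", "end_header"), fb)
  expect_error(load_spine_mesh(fb), "binary PLY")
})

test_that("z-correction scales only z and composes multiplicatively", {
  m <- tri_mesh(rbind(c(1, 2, 1), c(0, 0, 0), c(1, 0, 0), c(0, 1, 1)),
                rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 2), c(2, 4, 3)))
  mz <- apply_z_correction(m, 0.84)
  expect_equal(mz$vertices[1, ], c(1, 2, 0.84))
  expect_equal(mz$vertices[, 1:2], m$vertices[, 1:2])
  expect_identical(apply_z_correction(m, 1), m)
  expect_error(apply_z_correction(m, 0), "positive")

  # composition a*b == sequential a then b
  ab <- apply_z_correction(m, 0.6 * 0.7)
  seq2 <- apply_z_correction(apply_z_correction(m, 0.6), 0.7)
  expect_equal(ab$vertices, seq2$vertices)

  # volume of a cube halves under factor 0.5 (signed-volume oracle)
  cube <- cube_mesh()
  v0 <- signed_volume(cube)
  expect_equal(signed_volume(apply_z_correction(cube, 0.5)), v0 / 2,
               tolerance = 1e-12)
})

test_that("manifest validation reports all problems with spine ids", {
  d <- withr::local_tempdir()
  write_obj(spineA()$spine$mesh, file.path(d, "a.obj"))
  ok <- list(unit_scale = 1, z_correction = 1,
             spines = list(list(id = "s1", path = "a.obj",
                                insertion_point = c(0, 0, 0),
                                species = "human", compartment = "basal")))
  jf <- file.path(d, "m.json")
  jsonlite::write_json(ok, jf, auto_unbox = TRUE)
  man <- load_manifest(jf)
  expect_equal(length(man$spines), 1)
  sp <- load_dataset(man)
  expect_s3_class(sp[[1]], "spine_mesh")

  bad <- ok
  bad$spines[[1]]$insertion_point <- NULL
  bad$spines[[2]] <- list(id = "s2", path = "a.obj",
                          insertion_point = c(0, 0, 0))
  bad$spines[[3]] <- list(id = "s2", path = "a.obj",
                          insertion_point = c(0, 0, 0))
  jsonlite::write_json(bad, jf, auto_unbox = TRUE)
  err <- tryCatch(load_manifest(jf), error = conditionMessage)
  expect_match(err, "s1")
  expect_match(err, "duplicate spine_id: s2")
})

test_that("z-correction is applied once at dataset load, to mesh and anchor", {
  d <- withr::local_tempdir()
  write_obj(spineA()$spine$mesh, file.path(d, "a.obj"))
  man <- list(unit_scale = 2, z_correction = 0.5,
              spines = list(list(id = "s", path = "a.obj",
                                 insertion_point = c(1, 1, 1))))
  jf <- file.path(d, "m.json")
  jsonlite::write_json(man, jf, auto_unbox = TRUE)
  sp <- load_dataset(jf)[[1]]
  v0 <- spineA()$spine$mesh$vertices
  expect_equal(sp$mesh$vertices[, 1:2], 2 * v0[, 1:2])
  expect_equal(sp$mesh$vertices[, 3], v0[, 3])  # 2 * 0.5
  expect_equal(sp$insertion_point, c(2, 2, 1))
})

test_that("records round-trip through CSV with missingness preserved", {
  r1 <- data.frame(spine_id = "a", group = "A", repaired = FALSE,
                   head_volume_um3 = 0.123456789, head_area_um2 = 1.23,
                   sphericity = 0.91, neck_length_um = 0.6,
                   neck_diameter_nm = 301.5, spine_length_um = 1.6,
                   spine_volume_um3 = 0.55, species = "human",
                   compartment = "basal", subject_id = "h1",
                   dendrite_id = "d1")
  r2 <- r1
  r2$spine_id <- "b"; r2$group <- "C"; r2$repaired <- TRUE
  r2$neck_diameter_nm <- NA_real_
  f <- withr::local_tempfile(fileext = ".csv")
  write_records(rbind(r1, r2), f)
  back <- read_records(f)
  expect_equal(nrow(back), 2)
  expect_equal(back$head_volume_um3, c(r1$head_volume_um3, r2$head_volume_um3),
               tolerance = 1e-9)
  expect_true(is.na(back$neck_diameter_nm[2]))
  # empty cell, not zero, in the raw text
  raw <- readLines(f)
  expect_false(grepl(",0,", strsplit(raw[length(raw)], "301.5")[[1]][1]))
  expect_error(write_records(r1[0, ], f), "non-empty")
})

test_that("loading is idempotent and components survive reindexing", {
  m <- spineA()$spine$mesh
  f <- withr::local_tempfile(fileext = ".obj")
  write_obj(m, f)
  m2 <- load_spine_mesh(f)
  f2 <- withr::local_tempfile(fileext = ".obj")
  write_obj(m2, f2)
  m3 <- load_spine_mesh(f2)
  expect_equal(m2$vertices, m3$vertices, tolerance = 1e-9)
  expect_identical(m2$faces, m3$faces)

  # permute vertices: component count invariant
  set.seed(1)
  pm <- sample(nrow(m$vertices))
  inv <- integer(length(pm)); inv[pm] <- seq_along(pm)
  mp <- tri_mesh(m$vertices[pm, ], matrix(inv[m$faces], ncol = 3))
  expect_equal(mesh_component_count(mp), mesh_component_count(m))
})

test_that("degenerate faces are dropped with a message", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3), c(1, 1, 2))
  expect_message(m <- tri_mesh(v, f), "1 degenerate")
  expect_equal(nrow(m$faces), 4)
})
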