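test_that("skeletonization recovers tubular length and collapses spheres", {
  cyl <- cylinder_mesh(length = 2, radius = 0.15)
  sk <- skeletonize(cyl)
  expect_false(sk$collapsed)
  expect_gt(skeleton_length(sk), 1.8)
  expect_lt(skeleton_length(sk), 2.2)

  sph <- sphere_mesh(0.5, c(0, 0, 0.5), res = 1)
  sk2 <- skeletonize(sph)
  expect_true(sk2$collapsed)
  expect_equal(nrow(sk2$nodes), 1)
  expect_equal(as.numeric(sk2$nodes), c(0, 0, 0.5), tolerance = 0.1)

  expect_error(skeletonize(tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0),
                                          c(0, 1, 0), c(0, 0, 1)),
                                    rbind(c(1, 3, 2), c(1, 2, 4),
                                          c(2, 3, 4), c(1, 4, 3)))),
               "50 faces")
})

test_that("bent tubes keep their arc length in the skeleton", {
  s <- make_spine(neck_length = 2, neck_radius = 0.12,
                  head_radii = c(0.25, 0.25, 0.25), neck_curvature = 90,
                  seed = 1, mesh_resolution = 1)
  sk <- skeletonize(s$spine$mesh)
  # neck arc 2.0 um plus a short head contribution
  expect_gt(skeleton_length(sk), 1.8)
  expect_lt(skeleton_length(sk), 2.7)
})

test_that("SDF approximates local diameter on canonical shapes", {
  cyl <- cylinder_mesh(length = 2, radius = 0.15)
  sdf <- compute_sdf(cyl)
  cen <- face_centroids(cyl)
  mid <- cen[, 3] > 0.7 & cen[, 3] < 1.3
  expect_equal(median(sdf[mid]), 0.30, tolerance = 0.1)

  sph <- sphere_mesh(0.4, c(0, 0, 0), res = 1)
  sdf2 <- compute_sdf(sph)
  expect_equal(median(sdf2), 0.8, tolerance = 0.1)
  # all faces see roughly the same diameter on a sphere
  expect_lt(stats::IQR(sdf2) / median(sdf2), 0.2)

  # group-A spine: per-face SDF is bimodal with modes near 2*r_neck and
  # 2*r_head
  s <- spineA()
  sdf3 <- compute_sdf(s$spine$mesh)
  neck <- s$truth$face_labels == "neck"
  expect_equal(median(sdf3[neck]), 0.30, tolerance = 0.12)
  expect_equal(median(sdf3[!neck]), 1.0, tolerance = 0.15)
})

test_that("soft clustering maps the thinner component to the neck", {
  s <- spineA()
  labs <- spineA_sep()
  sc <- soft_cluster(labs$features)
  expect_true(sc$separable)
  hard <- ifelse(sc$posterior[, "neck"] > 0.5, "neck", "head")
  expect_lt(mean(labs$features$sdf[hard == "neck"]),
            mean(labs$features$sdf[hard == "head"]))
  expect_true(all(abs(rowSums(sc$posterior) - 1) < 1e-9))

  # identical features: degenerate, not separable
  flat <- data.frame(sdf = rep(1, 100), skel_dist = rep(0.5, 100))
  expect_false(soft_cluster(flat)$separable)
})

test_that("graph cut at lambda 0 equals the posterior argmax", {
  s <- spineA()
  sc <- soft_cluster(spineA_sep()$features)
  lab0 <- graph_cut_refine(s$spine$mesh, sc$posterior,
                           segmentation_params(smoothing_lambda = 0),
                           absorb = FALSE)
  argmax <- factor(ifelse(sc$posterior[, "head"] >= sc$posterior[, "neck"],
                          "head", "neck"), levels = c("head", "neck"))
  expect_identical(lab0, argmax)
})

test_that("the minimum cut never exceeds the argmax energy", {
  s <- spineA()
  mesh <- s$spine$mesh
  params <- segmentation_params(smoothing_lambda = 0.5)
  set.seed(8)
  for (rep in 1:3) {
    # noisy posteriors around the truth
    p_head <- ifelse(s$truth$face_labels == "head", 0.8, 0.2) +
      stats::runif(nrow(mesh$faces), -0.3, 0.3)
    p_head <- pmin(pmax(p_head, 0.01), 0.99)
    post <- cbind(head = p_head, neck = 1 - p_head)
    lab <- graph_cut_refine(mesh, post, params, absorb = FALSE)
    argmax <- factor(ifelse(post[, 1] >= post[, 2], "head", "neck"),
                     levels = c("head", "neck"))
    expect_lte(cut_energy(mesh, post, lab, params),
               cut_energy(mesh, post, argmax, params) + 1e-9)
    # and the smoothed labels stay close to the truth
    expect_gt(mean(as.character(lab) == s$truth$face_labels), 0.9)
  }
})

test_that("a dominant smoothness term yields a single label", {
  # uniform-ish posteriors: any cut costs more than it saves
  s <- make_spine(seed = 2, mesh_resolution = 1)
  nf <- nrow(s$spine$mesh$faces)
  set.seed(1)
  p <- pmin(pmax(0.5 + stats::rnorm(nf, 0, 0.02), 0.01), 0.99)
  lab <- graph_cut_refine(s$spine$mesh, cbind(head = p, neck = 1 - p),
                          segmentation_params(smoothing_lambda = 1),
                          absorb = FALSE)
  expect_equal(length(unique(as.character(lab))), 1)
})

test_that("separate distinguishes group A from group B morphologies", {
  labs <- spineA_sep()
  expect_true(labs$separable)
  expect_gte(mean(as.character(labs$labels) == spineA()$truth$face_labels),
             0.9)
  # the face nearest the insertion point is neck
  cen <- face_centroids(spineA()$spine$mesh)
  base <- which.min(rowSums(cen^2))
  expect_equal(as.character(labs$labels[base]), "neck")

  sB <- make_spine(target_group = "B", seed = 11, mesh_resolution = 1)
  labB <- separate(sB$spine)
  expect_false(labB$separable)

  # a bare sphere is one geometric population: not separable
  sph <- sphere_mesh(0.5, c(0, 0, 0.7), res = 1)
  spsph <- spine_mesh(sph, c(0, 0, 0.2), spine_id = "sph")
  expect_false(separate(spsph)$separable)

  expect_error(separate(make_spine(target_group = "D", seed = 1,
                                   mesh_resolution = 1)$spine),
               "single-component")
})

test_that("labels are invariant under rigid motion and uniform scale", {
  s <- make_spine(seed = 12, mesh_resolution = 1)
  labs <- separate(s$spine)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
    rbind(c(1, 0, 0), c(0, cos(0.4), -sin(0.4)), c(0, sin(0.4), cos(0.4)))
  sc <- 2.5
  m2 <- s$spine$mesh
  m2$vertices <- sc * (m2$vertices %*% t(R)) + rep(1, nrow(m2$vertices)) %o% c(3, -2, 1)
  sp2 <- spine_mesh(m2, sc * as.numeric(R %*% c(0, 0, 0)) + c(3, -2, 1),
                    spine_id = "moved")
  labs2 <- separate(sp2)
  expect_equal(labs2$separable, labs$separable)
  expect_gt(mean(labs2$labels == labs$labels), 0.98)
})
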