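# Shared fixtures, built in code and memoized per test session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# unit cube (12 triangles, outward orientation)
cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side), z = c(0, side)))
  f <- rbind(
    c(1, 3, 7), c(1, 7, 5),   # y-z at x: bottom z=0 plane? (indices per grid)
    c(2, 8, 4), c(2, 6, 8),
    c(1, 5, 6), c(1, 6, 2),
    c(3, 4, 8), c(3, 8, 7),
    c(1, 2, 4), c(1, 4, 3),
    c(5, 7, 8), c(5, 8, 6))
  m <- tri_mesh(v, f)
  if (signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# capped straight tube along z
cylinder_mesh <- function(length = 2, radius = 0.15, nt = 24, nz = 24) {
  rings <- lapply(seq(0, length, length.out = nz + 1), function(z)
    spinemorph:::ring_at(nt, radius, radius, z))
  spinemorph:::lathe(rings, cap_first = c(0, 0, 0),
                     cap_last = c(0, 0, length))$mesh
}

# closed sphere (lathe) of radius r centered at `center`
sphere_mesh <- function(r = 0.5, center = c(0, 0, 0), res = 2) {
  out <- spinemorph:::build_spine_C(c(r, r, r), gap = 1, res = res, rn = 0.1)
  m <- out$mesh
  m$vertices <- sweep(m$vertices, 2, c(0, 0, 1 + r) - center, "-")
  m
}

# default group-A spine, memoized (sphere head r=0.5, neck 0.6 x 0.15)
spineA <- function() fixture("spineA", function()
  make_spine(seed = 1, mesh_resolution = 1))

spineA_sep <- function() fixture("spineA_sep", function()
  separate(spineA()$spine))

tetra_obj_lines <- function(offset = c(0, 0, 0)) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  v <- sweep(v, 2, offset, "+")
  c(sprintf("v %g %g %g", v[, 1], v[, 2], v[, 3]),
    "f 1 3 2", "f 1 2 4", "f 2 3 4", "f 1 4 3")
}

# exact Mann-Whitney two-sided p by explicit enumeration over combn
mw_enum_oracle <- function(x, y) {
  m <- length(x)
  r <- rank(c(x, y))
  N <- length(r)
  mu <- m * (N - m) / 2
  us <- apply(utils::combn(N, m), 2, function(idx)
    sum(r[idx]) - m * (m + 1) / 2)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# labeling energy of the graph-cut objective
cut_energy <- function(mesh, posteriors, lab, params = segmentation_params()) {
  p <- pmin(pmax(posteriors, 1e-3), 1 - 1e-3)
  data_cost <- sum(ifelse(lab == "head", -log(p[, 1]), -log(p[, 2])))
  adj <- face_adjacency(mesh)
  nrm <- face_normals(mesh)
  cen <- face_centroids(mesh)
  n1 <- nrm[adj[, 1], , drop = FALSE]
  n2 <- nrm[adj[, 2], , drop = FALSE]
  alpha <- acos(pmin(pmax(rowSums(n1 * n2), -1), 1))
  conc <- rowSums((cen[adj[, 2], , drop = FALSE] -
                     cen[adj[, 1], , drop = FALSE]) * n1) > 1e-12
  w <- rep(10, nrow(adj))
  w[conc] <- pmin(pmax(-log(pmax(alpha[conc], 1e-9) / pi), 1e-6), 10)
  data_cost + params$smoothing_lambda *
    sum(w[lab[adj[, 1]] != lab[adj[, 2]]])
}
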