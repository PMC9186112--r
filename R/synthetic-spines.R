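#' Generate a synthetic spine mesh with known ground truth
#'
#' Builds a parametric dendritic spine as a lathed surface: an ellipsoidal
#' head (semi-axes `head_radii`, micrometers) truncated where it meets a
#' tubular neck of radius `neck_radius` and axial length `neck_length`,
#' based at the insertion point (the origin). The weld ring between the two
#' primitives is the ground-truth head/neck boundary, so every face carries
#' an unambiguous true label. Degraded variants emulate the completeness
#' classes produced by light-microscopy reconstruction pipelines:
#'
#' * `"A"` complete spine, head and neck, one watertight component;
#' * `"B"` sessile spine: wide, nearly zero-length collar under the head, one
#'   component that should not be separable into head and neck;
#' * `"C"` detached head only; the neck is invisible, leaving a gap of
#'   `neck_length` between the insertion point and the mesh;
#' * `"D"` two components: a basal neck fragment plus the head (with a neck
#'   stub);
#' * `"E"` three or more components (an extra floating fragment), which the
#'   analysis pipeline discards.
#'
#' @param head_radii three ellipsoid semi-axes (micrometers).
#' @param neck_length neck axis length, micrometers (for group C: the gap).
#' @param neck_radius neck tube radius, micrometers.
#' @param neck_curvature optional bend of the neck axis in degrees (arc
#'   length is preserved).
#' @param mesh_resolution integer subdivision level (>= 1); 1 gives a coarse
#'   mesh of a few hundred faces.
#' @param target_group `"A"`..`"E"`.
#' @param jitter_sd optional vertex jitter, as a fraction of `neck_radius`
#'   (Gaussian, applied to all coordinates); default 0 for oracle tests.
#' @param seed integer seed controlling all randomness in this call.
#' @param species,compartment,spine_id metadata passed to [spine_mesh()].
#' @return list with `spine` (a [spine_mesh()]) and `truth` (list:
#'   `head_volume`, `head_area`, `neck_length`, `neck_diameter`,
#'   `face_labels` (character, `"head"`/`"neck"`), `insertion_point`,
#'   `group`).
#' @export
make_spine <- function(head_radii = c(0.5, 0.5, 0.5), neck_length = 0.6,
                       neck_radius = 0.15, neck_curvature = 0,
                       mesh_resolution = 2, target_group = "A",
                       jitter_sd = 0, seed = 1L,
                       species = "human", compartment = "basal",
                       spine_id = "synthetic") {
  target_group <- match.arg(target_group, c("A", "B", "C", "D", "E"))
  if (any(head_radii <= 0) || neck_length <= 0 || neck_radius <= 0)
    stop("all spine dimensions must be positive")
  if (mesh_resolution < 1) stop("mesh_resolution must be >= 1")
  if (target_group == "C" && neck_length < 0.2)
    stop("group C requires the insertion point at least 0.2 um from the mesh")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  out <- switch(target_group,
                A = build_spine_A(head_radii, neck_length, neck_radius,
                                  neck_curvature, mesh_resolution),
                B = build_spine_B(head_radii, mesh_resolution),
                C = build_spine_C(head_radii, neck_length, mesh_resolution,
                                  neck_radius),
                D = build_spine_D(head_radii, neck_length, neck_radius,
                                  mesh_resolution),
                E = build_spine_E(head_radii, neck_length, neck_radius,
                                  mesh_resolution))
  mesh <- out$mesh
  if (jitter_sd > 0) {
    mesh$vertices <- mesh$vertices +
      matrix(stats::rnorm(length(mesh$vertices), 0, jitter_sd * neck_radius),
             ncol = 3)
  }
  sp <- spine_mesh(mesh, c(0, 0, 0), species = species,
                   compartment = compartment, spine_id = spine_id)
  truth <- out$truth
  truth$insertion_point <- c(0, 0, 0)
  truth$group <- target_group
  list(spine = sp, truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# approximate ellipsoid surface area (Thomsen's formula, p = 1.6075)
ellipsoid_area <- function(a, b, c) {
  p <- 1.6075
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

# Lathe builder: rings is a list of n x 3 matrices (equal n, ordered along
# the axis); consecutive rings are joined by triangle strips. cap_first /
# cap_last optionally close the ends with a fan to the given apex point.
# Returns mesh + per-face ring-interval index (1 = between ring 1 and 2 ...);
# cap faces get interval 0 (first) or length(rings) (last).
lathe <- function(rings, cap_first = NULL, cap_last = NULL) {
  nt <- nrow(rings[[1]])
  nr <- length(rings)
  verts <- do.call(rbind, rings)
  faces <- list()
  band <- integer(0)
  for (k in seq_len(nr - 1)) {
    o1 <- (k - 1) * nt
    o2 <- k * nt
    for (j in seq_len(nt)) {
      j2 <- if (j == nt) 1L else j + 1L
      faces[[length(faces) + 1L]] <- c(o1 + j, o1 + j2, o2 + j2)
      faces[[length(faces) + 1L]] <- c(o1 + j, o2 + j2, o2 + j)
      band <- c(band, k, k)
    }
  }
  if (!is.null(cap_first)) {
    verts <- rbind(verts, cap_first)
    ci <- nrow(verts)
    for (j in seq_len(nt)) {
      j2 <- if (j == nt) 1L else j + 1L
      faces[[length(faces) + 1L]] <- c(j2, j, ci)   # points outward (-axis)
      band <- c(band, 0L)
    }
  }
  if (!is.null(cap_last)) {
    verts <- rbind(verts, cap_last)
    ci <- nrow(verts)
    o <- (nr - 1) * nt
    for (j in seq_len(nt)) {
      j2 <- if (j == nt) 1L else j + 1L
      faces[[length(faces) + 1L]] <- c(o + j, o + j2, ci)
      band <- c(band, nr)
    }
  }
  list(mesh = tri_mesh(verts, do.call(rbind, faces), drop_degenerate = FALSE),
       band = band)
}

# ring of nt points: ellipse semi-axes (rx, ry) at height z
ring_at <- function(nt, rx, ry, z) {
  th <- seq(0, 2 * pi, length.out = nt + 1)[-(nt + 1)]
  cbind(rx * cos(th), ry * sin(th), z)
}

# bend warp: points with z in [0, L] follow a circular arc of total angle
# beta (degrees) in the x-z plane; points beyond L move rigidly with the arc
# end frame. Arc length along the axis is preserved.
bend_warp <- function(V, L, beta_deg) {
  if (beta_deg == 0) return(V)
  beta <- beta_deg * pi / 180
  R <- L / beta
  out <- V
  for (i in seq_len(nrow(V))) {
    x <- V[i, 1]; y <- V[i, 2]; z <- V[i, 3]
    if (z <= L) {
      al <- beta * z / L
      axis <- c(R * (1 - cos(al)), 0, R * sin(al))
      out[i, ] <- axis + x * c(cos(al), 0, -sin(al)) + c(0, y, 0)
    } else {
      al <- beta
      axis <- c(R * (1 - cos(al)), 0, R * sin(al))
      dz <- z - L
      out[i, ] <- axis + x * c(cos(al), 0, -sin(al)) + c(0, y, 0) +
        dz * c(sin(al), 0, cos(al))
    }
  }
  out
}

# Head ring stack: ellipsoid (a, b, c) truncated at polar angle phi0
# (measured from the pole facing the neck), center placed so the truncation
# ring sits at height z_base. Returns list(rings, junction_rx_ry).
head_rings <- function(a, b, c, phi0, nt, n_phi, z_base) {
  zc <- z_base + c * cos(phi0)
  phis <- seq(phi0, pi, length.out = n_phi + 1)  # last is the far pole
  rings <- lapply(phis[-length(phis)], function(ph)
    ring_at(nt, a * sin(ph), b * sin(ph), zc - c * cos(ph)))
  list(rings = rings, pole = c(0, 0, zc + c))
}

build_spine_A <- function(hr, L, rn, curv, res) {
  a <- hr[1]; b <- hr[2]; c <- hr[3]
  nt <- 14 * res + 6
  phi0 <- asin(min(0.95, rn / min(a, b)))
  n_neck <- max(3L, ceiling(L / (0.1 / res)))
  n_phi <- max(10L, 9 * res)
  # neck rings: circular at base, blending into the elliptical junction ring
  svals <- seq(0, 1, length.out = n_neck + 1)
  jr <- c(a * sin(phi0), b * sin(phi0))
  neck <- lapply(svals, function(s) {
    w <- s^4
    ring_at(nt, (1 - w) * rn + w * jr[1], (1 - w) * rn + w * jr[2], s * L)
  })
  hd <- head_rings(a, b, c, phi0, nt, n_phi, L)
  rings <- c(neck, hd$rings[-1])  # head ring 1 coincides with last neck ring
  lt <- lathe(rings, cap_first = c(0, 0, 0), cap_last = hd$pole)
  n_rings <- length(rings)
  # bands 1..n_neck are neck tube; 0 is base cap; > n_neck is head
  labels <- ifelse(lt$band <= n_neck, "neck", "head")
  mesh <- lt$mesh
  mesh$vertices <- bend_warp(mesh$vertices, L, curv)
  list(mesh = mesh,
       truth = list(head_volume = 4 / 3 * pi * a * b * c,
                    head_area = ellipsoid_area(a, b, c),
                    neck_length = L, neck_diameter = 2 * rn,
                    face_labels = labels))
}

# sessile head: an ellipsoid dome seated directly on the dendrite surface,
# truncated below its equator (base ring at 85% of the full width), with no
# collar or neck at all - every cross-section is head-like, so there is no
# thin compartment for a separation to latch onto
build_spine_B <- function(hr, res) {
  a <- hr[1]; b <- hr[2]; c <- hr[3]
  nt <- 14 * res + 6
  phi0 <- asin(0.85)
  hd <- head_rings(a, b, c, phi0, nt, max(12L, 10 * res), 0)
  lt <- lathe(hd$rings, cap_first = c(0, 0, 0), cap_last = hd$pole)
  labels <- rep("head", nrow(lt$mesh$faces))
  list(mesh = lt$mesh,
       truth = list(head_volume = 4 / 3 * pi * a * b * c,
                    head_area = ellipsoid_area(a, b, c),
                    neck_length = 0, neck_diameter = NA_real_,
                    face_labels = labels))
}

# full closed ellipsoid centered above a gap: the invisible-neck case
build_spine_C <- function(hr, gap, res, rn) {
  a <- hr[1]; b <- hr[2]; c <- hr[3]
  nt <- 14 * res + 6
  n_phi <- max(12L, 12 * res)
  zc <- gap + c
  phis <- seq(0, pi, length.out = n_phi + 1)
  rings <- lapply(phis[-c(1, n_phi + 1)], function(ph)
    ring_at(nt, a * sin(ph), b * sin(ph), zc - c * cos(ph)))
  lt <- lathe(rings, cap_first = c(0, 0, zc - c), cap_last = c(0, 0, zc + c))
  list(mesh = lt$mesh,
       truth = list(head_volume = 4 / 3 * pi * a * b * c,
                    head_area = ellipsoid_area(a, b, c),
                    neck_length = gap, neck_diameter = 2 * rn,
                    face_labels = rep("head", nrow(lt$mesh$faces))))
}

# two components: basal neck fragment + head with a neck stub
build_spine_D <- function(hr, L, rn, res, frag_end = 0.45, head_start = 0.55) {
  nt <- 14 * res + 6
  # fragment: capped tube from 0 to frag_end * L
  n1 <- max(2L, ceiling(frag_end * L / (0.1 / res)))
  rings1 <- lapply(seq(0, frag_end * L, length.out = n1 + 1), function(z)
    ring_at(nt, rn, rn, z))
  frag <- lathe(rings1, cap_first = c(0, 0, 0),
                cap_last = c(0, 0, frag_end * L))
  # head part: group-A spine whose neck starts at head_start * L
  a <- hr[1]; b <- hr[2]; c <- hr[3]
  phi0 <- asin(min(0.95, rn / min(a, b)))
  jr <- c(a * sin(phi0), b * sin(phi0))
  n2 <- max(2L, ceiling((1 - head_start) * L / (0.1 / res)))
  svals <- seq(0, 1, length.out = n2 + 1)
  neck2 <- lapply(svals, function(s) {
    w <- s^4
    z <- head_start * L + s * (1 - head_start) * L
    ring_at(nt, (1 - w) * rn + w * jr[1], (1 - w) * rn + w * jr[2], z)
  })
  hd <- head_rings(a, b, c, phi0, nt, max(10L, 9 * res), L)
  upper <- lathe(c(neck2, hd$rings[-1]),
                 cap_first = c(0, 0, head_start * L), cap_last = hd$pole)
  mesh <- merge_meshes(frag$mesh, upper$mesh)
  labels <- c(rep("neck", nrow(frag$mesh$faces)),
              ifelse(upper$band <= n2, "neck", "head"))
  list(mesh = mesh,
       truth = list(head_volume = 4 / 3 * pi * a * b * c,
                    head_area = ellipsoid_area(a, b, c),
                    neck_length = L, neck_diameter = 2 * rn,
                    face_labels = labels))
}

build_spine_E <- function(hr, L, rn, res) {
  d <- build_spine_D(hr, L, rn, res)
  # extra floating fragment: a small sphere beside the neck
  nt <- 8
  r <- 0.6 * rn
  cen <- c(3 * rn + max(hr), 0, 0.5 * L)
  phis <- seq(0, pi, length.out = 6)
  rings <- lapply(phis[-c(1, 6)], function(ph)
    ring_at(nt, r * sin(ph), r * sin(ph), cen[3] - r * cos(ph)))
  rings <- lapply(rings, function(rg) {
    rg[, 1] <- rg[, 1] + cen[1]; rg[, 2] <- rg[, 2] + cen[2]; rg
  })
  blob <- lathe(rings, cap_first = cen - c(0, 0, r), cap_last = cen + c(0, 0, r))
  mesh <- merge_meshes(d$mesh, blob$mesh)
  truth <- d$truth
  truth$face_labels <- c(truth$face_labels,
                         rep("neck", nrow(blob$mesh$faces)))
  list(mesh = mesh, truth = truth)
}

#' Sample a synthetic morphometric population
#'
#' Draws per-spine feature tables from log-normal marginals coupled by a
#' Gaussian copula, emulating the skewed, unimodal, positively correlated
#' feature distributions reported for spine morphometry datasets. Medians and
#' multiplicative spreads are specified per feature; rank correlations are
#' targeted through the copula (Pearson correlation of the latent Gaussians
#' set to `2*sin(pi*rho_s/6)`).
#'
#' @param n number of spines.
#' @param medians named numeric vector of feature medians (any features).
#' @param sdlogs log-scale standard deviations, same names/order.
#' @param rank_cor target Spearman correlation matrix (or NULL for
#'   independence).
#' @param seed integer seed.
#' @return data.frame with `n` rows and one column per feature.
#' @export
sample_population <- function(n,
                              medians = c(head_volume_um3 = 0.32,
                                          neck_length_um = 0.594,
                                          neck_diameter_nm = 339),
                              sdlogs = c(head_volume_um3 = 0.7,
                                         neck_length_um = 0.7,
                                         neck_diameter_nm = 0.33),
                              rank_cor = NULL, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (any(medians <= 0)) stop("medians must be positive")
  if (any(sdlogs < 0)) stop("sdlogs must be non-negative")
  k <- length(medians)
  if (length(sdlogs) != k) stop("medians and sdlogs must have equal length")
  if (is.null(rank_cor)) rank_cor <- diag(k)
  rank_cor <- as.matrix(rank_cor)
  pearson <- 2 * sin(pi * rank_cor / 6)
  diag(pearson) <- 1
  ev <- eigen(pearson, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("rank correlation target is not positive semi-definite")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ch <- chol(pearson + diag(1e-10, k))
  z <- matrix(stats::rnorm(n * k), n, k) %*% ch
  x <- vapply(seq_len(k), function(j)
    stats::qlnorm(stats::pnorm(z[, j]), meanlog = log(medians[j]),
                  sdlog = sdlogs[j]),
    numeric(n))
  x <- matrix(x, nrow = n)
  colnames(x) <- names(medians)
  as.data.frame(x)
}

#' Bimodal reference samples for dip-test power checks
#'
#' Equal-weight mixture of two unit-variance Gaussians whose means are
#' `separation` standard deviations apart along the first axis (a negative
#' control for unimodality tests; `separation = 0` gives a single Gaussian).
#'
#' @param n sample size (>= 10).
#' @param separation distance between the component means, in SD units.
#' @param seed integer seed.
#' @param dim 1, 2 or 3.
#' @return numeric vector (`dim = 1`) or matrix with `dim` columns.
#' @export
make_bimodal_population <- function(n, separation, seed = 1L, dim = 1L) {
  if (n < 10) stop("n must be >= 10")
  if (separation < 0) stop("separation must be >= 0")
  if (!dim %in% 1:3) stop("dim must be 1, 2 or 3")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  comp <- stats::rbinom(n, 1, 0.5)
  x <- stats::rnorm(n) + comp * separation - separation / 2
  if (dim == 1L) return(x)
  cbind(x, matrix(stats::rnorm(n * (dim - 1)), n))
}

#' Write a synthetic fixture dataset (OBJ files + manifest + ground truth)
#'
#' @param specs list of argument lists for [make_spine()]; each must include
#'   a unique `spine_id`.
#' @param dir output directory (created if needed).
#' @return path of the manifest file, invisibly.
#' @export
write_fixture_dataset <- function(specs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  truths <- list()
  for (sp in specs) {
    made <- do.call(make_spine, sp)
    id <- made$spine$spine_id
    fn <- paste0(id, ".obj")
    write_obj(made$spine$mesh, file.path(dir, fn))
    entries[[length(entries) + 1L]] <-
      list(id = id, path = fn,
           insertion_point = as.numeric(made$spine$insertion_point),
           species = made$spine$species,
           compartment = made$spine$compartment)
    truths[[id]] <- made$truth[c("head_volume", "neck_length",
                                 "neck_diameter", "group")]
  }
  manifest <- list(unit_scale = 1, z_correction = 1, spines = entries)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(truths, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}
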