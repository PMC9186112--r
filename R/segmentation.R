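#' Segmentation parameters
#'
#' @param smoothing_lambda graph-cut smoothness weight in `[0, 1]`; 0.5 is
#'   the value appropriate for the relatively smooth meshes that
#'   light-microscopy reconstructions produce.
#' @param sdf_rays rays cast per face for the shape diameter function.
#' @param sdf_cone_deg full opening angle of the ray cone, degrees.
#' @param min_region_faces minimum faces per region for a separable call.
#' @param min_neck_length shortest measurable neck, micrometers; a putative
#'   neck below this (default 0.2, the light-microscopy resolution proxy
#'   also used as the repair anchor threshold) means the spine is sessile
#'   and not separable.
#' @param seed integer seed (kept for interface stability; the fitting
#'   pipeline is deterministic).
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_lambda = 0.5, sdf_rays = 25,
                                sdf_cone_deg = 120, min_region_faces = 5,
                                min_neck_length = 0.2, seed = 1L) {
  if (smoothing_lambda < 0 || smoothing_lambda > 1)
    stop("smoothing_lambda must be in [0, 1]")
  if (sdf_rays < 3) stop("sdf_rays must be >= 3")
  if (sdf_cone_deg <= 0 || sdf_cone_deg >= 180)
    stop("sdf_cone_deg must be in (0, 180)")
  structure(list(smoothing_lambda = smoothing_lambda, sdf_rays = sdf_rays,
                 sdf_cone_deg = sdf_cone_deg,
                 min_region_faces = min_region_faces,
                 min_neck_length = min_neck_length, seed = as.integer(seed)),
            class = "segmentation_params")
}

#' Shape diameter function
#'
#' Per-face local thickness: rays are cast from each face centroid into the
#' mesh interior within a cone around the inward normal; the chord lengths
#' are aggregated by a median after interquartile-range outlier rejection,
#' and the result is smoothed once over face neighbors. Holes are capped
#' before casting so chords terminate. Faces whose rays all miss are imputed
#' from their neighbors and flagged.
#'
#' @param mesh a `tri_mesh`.
#' @param params a [segmentation_params()].
#' @return numeric vector of per-face SDF values (micrometers) with
#'   attribute `imputed` (logical vector).
#' @export
compute_sdf <- function(mesh, params = segmentation_params()) {
  capped <- cap_holes(mesh)
  cm <- capped$mesh
  nf0 <- nrow(mesh$faces)
  cen <- face_centroids(cm)
  nrm <- face_normals(cm)
  hits <- .sdf_rays_cpp(cm$vertices, cm$faces, cen, nrm,
                        as.integer(params$sdf_rays), params$sdf_cone_deg / 2)
  # chords come back normalized by ray tilt (exact on spheres); a low
  # quantile after outlier rejection stays close to the true diameter on
  # tubes, where tilted rays overshoot
  agg <- apply(hits, 1, function(h) {
    h <- h[is.finite(h)]
    if (length(h) == 0) return(NA_real_)
    q <- stats::quantile(h, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    keep <- h >= q[1] - 1.5 * iqr & h <= q[2] + 1.5 * iqr
    stats::quantile(h[keep], 0.25, names = FALSE)
  })
  agg <- agg[seq_len(nf0)]
  imputed <- !is.finite(agg)
  adj <- face_adjacency(mesh)
  if (any(imputed)) {
    for (rep in 1:3) {
      for (f in which(!is.finite(agg))) {
        nb <- c(adj[adj[, 1] == f, 2], adj[adj[, 2] == f, 1])
        v <- agg[nb]
        v <- v[is.finite(v)]
        if (length(v)) agg[f] <- stats::median(v)
      }
      if (all(is.finite(agg))) break
    }
    agg[!is.finite(agg)] <- stats::median(agg[is.finite(agg)])
  }
  # one neighbor-smoothing pass
  sm <- agg
  nb1 <- split(c(adj[, 2], adj[, 1]), c(adj[, 1], adj[, 2]))
  for (f in seq_len(nf0)) {
    nb <- nb1[[as.character(f)]]
    if (!is.null(nb)) sm[f] <- mean(c(agg[f], agg[nb]))
  }
  attr(sm, "imputed") <- imputed
  sm
}

#' Two-component Gaussian-mixture soft clustering of face features
#'
#' Fits a bivariate two-component Gaussian mixture to standardized
#' `(sdf, skeleton distance)` features by EM, initialized from quantile
#' splits on the SDF (five deterministic restarts, best likelihood kept).
#' The component with the lower mean SDF is reported as `"neck"`.
#'
#' @param features matrix/data.frame with columns `sdf` and `skel_dist`.
#' @param params a [segmentation_params()].
#' @return list: `posterior` (n x 2 matrix, columns head/neck), `separable`
#'   (FALSE when the fit is degenerate), `means`, `loglik`.
#' @export
soft_cluster <- function(features, params = segmentation_params()) {
  X <- as.matrix(features[, c("sdf", "skel_dist")])
  n <- nrow(X)
  if (n < 4 || nrow(unique(X)) < 2)
    return(list(posterior = NULL, separable = FALSE,
                reason = "degenerate features"))
  Z <- scale(X)
  Z[, !is.finite(colSums(Z))] <- 0  # constant column: keep at 0
  best <- NULL
  for (q in c(0.5, 0.3, 0.7, 0.4, 0.6)) {
    init <- Z[, 1] <= stats::quantile(Z[, 1], q)
    if (length(unique(init)) < 2) next
    fit <- em_gmm2(Z, init)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    return(list(posterior = NULL, separable = FALSE,
                reason = "EM failed to fit two components"))
  # component with lower mean SDF (on the original scale) is the neck
  m_sdf <- vapply(1:2, function(k)
    stats::weighted.mean(X[, 1], best$post[, k]), numeric(1))
  neck <- which.min(m_sdf)
  if (abs(diff(m_sdf)) < 1e-12) {
    m_sk <- vapply(1:2, function(k)
      stats::weighted.mean(X[, 2], best$post[, k]), numeric(1))
    neck <- which.min(m_sk)  # tie: head has larger skeleton distance
  }
  post <- cbind(head = best$post[, 3 - neck], neck = best$post[, neck])
  wt <- colSums(post)
  sep <- all(wt >= 2) && best$sep
  reason <- NULL
  # components collapse: the putative neck must be distinctly thinner than
  # the head, otherwise the spine has no separable neck (group-B semantics)
  ratio <- m_sdf[3 - neck] / m_sdf[neck]
  if (!is.finite(ratio) || ratio < 1.3) {
    sep <- FALSE
    reason <- "mixture components collapse: no distinctly thinner neck"
  }
  list(posterior = post, separable = sep, means = best$means,
       loglik = best$loglik, sdf_ratio = ratio, reason = reason)
}

# plain EM for a 2-component bivariate Gaussian mixture
em_gmm2 <- function(Z, init, max_iter = 60, tol = 1e-8) {
  n <- nrow(Z)
  r <- cbind(as.numeric(init), as.numeric(!init))
  loglik <- -Inf
  for (it in seq_len(max_iter)) {
    w <- colMeans(r)
    if (any(w < 2 / n)) return(NULL)
    mu <- lapply(1:2, function(k) colSums(r[, k] * Z) / sum(r[, k]))
    sg <- lapply(1:2, function(k) {
      d <- sweep(Z, 2, mu[[k]])
      S <- crossprod(d * r[, k], d) / sum(r[, k])
      S + diag(1e-8, 2)
    })
    dens <- vapply(1:2, function(k) {
      S <- sg[[k]]
      det <- S[1, 1] * S[2, 2] - S[1, 2]^2
      if (det <= 1e-20) return(rep(NA_real_, n))
      Sinv <- matrix(c(S[2, 2], -S[1, 2], -S[1, 2], S[1, 1]), 2) / det
      d <- sweep(Z, 2, mu[[k]])
      q <- rowSums((d %*% Sinv) * d)
      w[k] * exp(-0.5 * q) / (2 * pi * sqrt(det))
    }, numeric(n))
    if (any(!is.finite(dens))) return(NULL)
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    r <- dens / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - loglik) < tol * (abs(loglik) + 1)) {
      loglik <- ll
      break
    }
    loglik <- ll
  }
  list(post = r, means = mu, loglik = loglik, sep = TRUE)
}

#' Graph-cut refinement of soft labels
#'
#' Minimizes `E = sum_f -log P(label_f) + lambda * sum_{f~g} w(theta) *
#' [label_f != label_g]` exactly via a single minimum s-t cut on the face
#' adjacency graph. The dihedral weight `w` makes cuts cheap at sharp
#' concave creases (the head-neck junction) and expensive across flat or
#' convex areas: for concave edges `w = clamp(-log(alpha/pi), 1e-6, 10)`
#' with `alpha` the angle between face normals, and `w = 10` for convex
#' edges.
#'
#' After the cut, disconnected label patches below 20% of their class are
#' absorbed into the other class (`absorb = FALSE` returns the raw minimum
#' cut, which is the exact minimizer of the energy above).
#'
#' @param mesh a `tri_mesh`.
#' @param posteriors n x 2 matrix (columns head, neck), rows summing to 1.
#' @param params a [segmentation_params()].
#' @param absorb apply the island post-process (default TRUE).
#' @return factor of per-face labels (`"head"`/`"neck"`).
#' @export
graph_cut_refine <- function(mesh, posteriors, params = segmentation_params(),
                             absorb = TRUE) {
  nf <- nrow(mesh$faces)
  stopifnot(nrow(posteriors) == nf)
  p <- pmin(pmax(posteriors, 1e-3), 1 - 1e-3)
  cost_head <- -log(p[, 1])
  cost_neck <- -log(p[, 2])
  lam <- params$smoothing_lambda
  adj <- face_adjacency(mesh)
  if (lam > 0 && nrow(adj) > 0) {
    nrm <- face_normals(mesh)
    cen <- face_centroids(mesh)
    n1 <- nrm[adj[, 1], , drop = FALSE]
    n2 <- nrm[adj[, 2], , drop = FALSE]
    dt <- pmin(pmax(rowSums(n1 * n2), -1), 1)
    alpha <- acos(dt)
    conc <- rowSums((cen[adj[, 2], , drop = FALSE] -
                       cen[adj[, 1], , drop = FALSE]) * n1) > 1e-12
    w <- rep(10, nrow(adj))
    w[conc] <- pmin(pmax(-log(pmax(alpha[conc], 1e-9) / pi), 1e-6), 10)
    wts <- lam * w
  } else {
    wts <- numeric(0)
    adj <- adj[0, , drop = FALSE]
  }
  s <- nf + 1L
  t <- nf + 2L
  from <- c(rep(s, nf), seq_len(nf), adj[, 1], adj[, 2])
  to <- c(seq_len(nf), rep(t, nf), adj[, 2], adj[, 1])
  cap <- c(cost_neck, cost_head, wts, wts)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  fl <- igraph::max_flow(g, source = s, target = t, capacity = cap)
  head_side <- as.integer(fl$partition1)
  lab <- rep("neck", nf)
  lab[head_side[head_side <= nf]] <- "head"
  if (absorb) absorb_islands(lab, mesh) else factor(lab, levels = c("head", "neck"))
}

# relabel small disconnected patches (< 20% of their class) into the other
# class; sharp concave creases can make cutting around such islands nearly
# free, so the smoothness term alone does not remove them. Connectivity is
# vertex-wise so vertex-welded repair cylinders count as connected.
absorb_islands <- function(lab, mesh, max_frac = 0.2, max_pass = 5) {
  for (pass in seq_len(max_pass)) {
    changed <- FALSE
    for (side in c("head", "neck")) {
      idx <- which(lab == side)
      if (length(idx) < 2) next
      cc <- face_components_vertexwise(mesh, idx)
      sizes <- tabulate(cc)
      if (length(sizes) <= 1) next
      main <- which.max(sizes)
      for (k in seq_along(sizes)) {
        if (k == main) next
        if (sizes[k] <= max_frac * length(idx)) {
          lab[idx[cc == k]] <- if (side == "head") "neck" else "head"
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  factor(lab, levels = c("head", "neck"))
}

#' Separate a spine mesh into head and neck
#'
#' Full unsupervised separation: curve-skeleton extraction, SDF and
#' skeleton-distance features, Gaussian-mixture soft clustering, graph-cut
#' smoothing, and a separability decision. A spine is declared separable
#' (complete-spine semantics) when both regions are non-empty with at least
#' `min_region_faces` faces, each region is face-connected, and the face
#' nearest the insertion point carries the neck label; otherwise the spine
#' has the "cannot be separated" semantics.
#'
#' @param spine a [spine_mesh()] (single component, native or repaired).
#' @param params a [segmentation_params()].
#' @return list of class `head_neck_labels`: `labels` (factor head/neck per
#'   face or NULL), `separable`, `boundary_edges`, `features` (data.frame
#'   sdf/skel_dist), `skeleton`, `reason` (when not separable).
#' @export
separate <- function(spine, params = segmentation_params()) {
  mesh <- spine$mesh
  if (mesh_component_count(mesh) != 1L)
    stop("separate() needs a single-component mesh; repair first")
  skel <- skeletonize(mesh)
  skel <- augment_skeleton(skel, spine$insertion_point)
  sdf <- compute_sdf(mesh, params)
  skd <- face_skeleton_distance(mesh, skel)
  features <- data.frame(sdf = as.numeric(sdf), skel_dist = skd)
  res <- structure(list(labels = NULL, separable = FALSE,
                        boundary_edges = NULL, features = features,
                        skeleton = skel, reason = NULL),
                   class = "head_neck_labels")
  sc <- soft_cluster(features, params)
  if (!isTRUE(sc$separable)) {
    res$reason <- sc$reason %||% "degenerate mixture fit"
    return(res)
  }
  lab <- graph_cut_refine(mesh, sc$posterior, params)
  res$labels <- lab
  tab <- table(lab)
  if (any(tab < params$min_region_faces)) {
    res$reason <- "a region is empty or below the minimum size"
    return(res)
  }
  for (side in c("head", "neck")) {
    cc <- face_components_vertexwise(mesh, which(lab == side))
    if (max(cc) != 1L) {
      res$reason <- sprintf("%s region is not connected", side)
      return(res)
    }
  }
  adj <- face_adjacency(mesh)
  cen <- face_centroids(mesh)
  base_face <- which.min(colSums((t(cen) - spine$insertion_point)^2))
  if (lab[base_face] != "neck") {
    res$reason <- "insertion point does not touch the neck region"
    return(res)
  }
  cut <- lab[adj[, 1]] != lab[adj[, 2]]
  res$boundary_edges <- adj[cut, , drop = FALSE]
  res$separable <- TRUE
  # a neck shorter than the resolution proxy is no neck: the cut has merely
  # shaved off the basal cap of a sessile spine
  nl <- tryCatch(as.numeric(neck_length(spine, res)), error = function(e) NA)
  if (!is.finite(nl) || nl < params$min_neck_length) {
    res$separable <- FALSE
    res$reason <- sprintf("putative neck is shorter than %g um",
                          params$min_neck_length)
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.head_neck_labels <- function(x, ...) {
  if (x$separable) {
    cat(sprintf("head/neck labels: separable (%d head, %d neck faces)\n",
                sum(x$labels == "head"), sum(x$labels == "neck")))
  } else {
    cat("head/neck labels: not separable:", x$reason %||% "", "\n")
  }
  invisible(x)
}
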