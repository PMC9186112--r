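#' Extract a curve skeleton from a spine mesh
#'
#' Mean-curvature-flow style contraction: vertices are iteratively drawn
#' toward the barycenter of their neighbors by solving the sparse
#' least-squares system `argmin ||wL * L v||^2 + ||wH (v - v_prev)||^2`
#' with a uniform graph Laplacian, with the contraction weight increased
#' each round until the surface has collapsed onto a quasi-1D set. The
#' collapsed vertices are then merged along short contracted edges
#' (union-find), merged clusters become skeleton nodes at their contracted
#' centroids, and nodes inherit edges from the mesh connectivity; a minimum
#' spanning tree in Euclidean edge length gives the final curve skeleton.
#' Sphere-like meshes collapse to a single node, which is flagged.
#'
#' @param mesh a single-component `tri_mesh` with at least 50 faces.
#' @param iterations number of contraction rounds.
#' @param w_contract initial contraction weight (relative to the unit
#'   attraction weight); doubled each round.
#' @return object of class `spine_skeleton`: `nodes` (k x 3 matrix),
#'   `edges` (two-column matrix of node indices, MST), `vertex_node`
#'   (node id per mesh vertex), `face_node` (node id per face),
#'   `collapsed` (TRUE when the skeleton is a single node).
#' @export
skeletonize <- function(mesh, iterations = 6, w_contract = 2) {
  nv <- nrow(mesh$vertices)
  if (mesh_component_count(mesh) != 1L)
    stop("skeletonize requires a single-component mesh")
  if (nrow(mesh$faces) < 50L)
    stop("mesh too coarse to skeletonize (< 50 faces)")
  et <- mesh_edge_table(mesh)
  eu <- unique(et[, c("v1", "v2")])
  # uniform Laplacian: row i -> mean of neighbors - self
  deg <- tabulate(c(eu$v1, eu$v2), nbins = nv)
  Adj <- Matrix::sparseMatrix(i = c(eu$v1, eu$v2), j = c(eu$v2, eu$v1),
                              x = 1, dims = c(nv, nv))
  Dinv <- Matrix::Diagonal(x = 1 / pmax(deg, 1))
  L <- Dinv %*% Adj - Matrix::Diagonal(nv)
  V <- mesh$vertices
  wl <- w_contract
  for (it in seq_len(iterations)) {
    A <- wl^2 * Matrix::crossprod(L) + Matrix::Diagonal(nv)
    V <- as.matrix(Matrix::solve(A, V))
    wl <- wl * 2
  }
  # merge vertices joined by short contracted edges
  elen0 <- sqrt(rowSums((mesh$vertices[eu$v1, , drop = FALSE] -
                           mesh$vertices[eu$v2, , drop = FALSE])^2))
  elen <- sqrt(rowSums((V[eu$v1, , drop = FALSE] -
                          V[eu$v2, , drop = FALSE])^2))
  thr <- 0.5 * stats::median(elen0)
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(elen)
  for (k in ord) {
    if (elen[k] >= thr) break
    a <- find(eu$v1[k]); b <- find(eu$v2[k])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(nv), find, integer(1))
  cl <- as.integer(factor(roots))
  k <- max(cl)
  nodes <- t(vapply(seq_len(k), function(g)
    colMeans(V[cl == g, , drop = FALSE]), numeric(3)))
  vertex_node <- cl
  # node graph from mesh edges crossing clusters
  ec <- cbind(cl[eu$v1], cl[eu$v2])
  ec <- ec[ec[, 1] != ec[, 2], , drop = FALSE]
  collapsed <- k == 1L
  edges <- matrix(integer(0), ncol = 2)
  if (!collapsed && nrow(ec) > 0) {
    ec <- unique(cbind(pmin(ec[, 1], ec[, 2]), pmax(ec[, 1], ec[, 2])))
    w <- sqrt(rowSums((nodes[ec[, 1], , drop = FALSE] -
                         nodes[ec[, 2], , drop = FALSE])^2))
    gr <- igraph::graph_from_edgelist(ec, directed = FALSE)
    igraph::E(gr)$weight <- w
    mst <- igraph::mst(gr)
    edges <- igraph::as_edgelist(mst)
    storage.mode(edges) <- "integer"
  }
  # contraction pulls tube ends inward; push each leaf back out along its
  # own direction by the axial extent of the original vertices it absorbed
  ext_nodes <- integer(0)
  if (!collapsed && nrow(edges) > 0) {
    deg <- tabulate(as.vector(edges), nbins = k)
    for (leaf in which(deg == 1L)) {
      e <- edges[edges[, 1] == leaf | edges[, 2] == leaf, , drop = FALSE][1, ]
      nb <- if (e[1] == leaf) e[2] else e[1]
      d <- nodes[leaf, ] - nodes[nb, ]
      nd <- sqrt(sum(d^2))
      if (nd == 0) next
      d <- d / nd
      vin <- mesh$vertices[cl == leaf, , drop = FALSE]
      proj <- as.vector(sweep(vin, 2, nodes[leaf, ]) %*% d)
      ext <- max(proj)
      if (ext > 1e-6) {
        # end node at the centroid of the extreme vertices, so curved tube
        # ends are followed rather than extrapolated
        sel <- proj >= 0.8 * ext
        tip <- colMeans(vin[sel, , drop = FALSE])
        if (sqrt(sum((tip - nodes[leaf, ])^2)) > 1e-6) {
          nodes <- rbind(nodes, tip)
          edges <- rbind(edges, c(leaf, nrow(nodes)))
          ext_nodes <- c(ext_nodes, nrow(nodes))
        }
      }
    }
    dimnames(nodes) <- NULL
  }
  fn <- apply(matrix(cl[mesh$faces], ncol = 3), 1, function(r) {
    tb <- table(r)
    as.integer(names(tb)[which.max(tb)])
  })
  structure(list(nodes = nodes, edges = edges, vertex_node = vertex_node,
                 face_node = fn, collapsed = collapsed,
                 ext_nodes = ext_nodes, contracted = V),
            class = "spine_skeleton")
}

#' @exportS3Method base::print
print.spine_skeleton <- function(x, ...) {
  cat(sprintf("spine_skeleton: %d node(s), %d edge(s)%s\n",
              nrow(x$nodes), nrow(x$edges),
              if (x$collapsed) " [collapsed to a point]" else ""))
  invisible(x)
}

#' Total skeleton length
#'
#' Sum of Euclidean lengths of the skeleton's (MST) edges.
#'
#' @param skel a `spine_skeleton`.
#' @return length in micrometers (0 for a collapsed skeleton).
#' @export
skeleton_length <- function(skel) {
  if (nrow(skel$edges) == 0) return(0)
  sum(sqrt(rowSums((skel$nodes[skel$edges[, 1], , drop = FALSE] -
                      skel$nodes[skel$edges[, 2], , drop = FALSE])^2)))
}

# graph of the skeleton with edge weights = Euclidean length
skeleton_graph <- function(skel) {
  gr <- igraph::make_empty_graph(n = nrow(skel$nodes), directed = FALSE)
  if (nrow(skel$edges) > 0) {
    w <- sqrt(rowSums((skel$nodes[skel$edges[, 1], , drop = FALSE] -
                         skel$nodes[skel$edges[, 2], , drop = FALSE])^2))
    gr <- igraph::add_edges(gr, t(skel$edges))
    igraph::E(gr)$weight <- w
  }
  gr
}

# arc length between two nodes along the skeleton
skeleton_arc_length <- function(skel, from, to) {
  if (from == to) return(0)
  gr <- skeleton_graph(skel)
  d <- igraph::distances(gr, v = from, to = to)[1, 1]
  as.numeric(d)
}

# nearest skeleton node to a 3D point
nearest_node <- function(skel, p) {
  which.min(colSums((t(skel$nodes) - p)^2))
}

# distance from each face centroid to the skeleton curve (nodes + segments)
face_skeleton_distance <- function(mesh, skel) {
  cen <- face_centroids(mesh)
  nd <- skel$nodes
  d2 <- vapply(seq_len(nrow(cen)), function(i)
    min(colSums((t(nd) - cen[i, ])^2)), numeric(1))
  if (nrow(skel$edges) > 0) {
    for (k in seq_len(nrow(skel$edges))) {
      a <- nd[skel$edges[k, 1], ]
      b <- nd[skel$edges[k, 2], ]
      ab <- b - a
      len2 <- sum(ab^2)
      if (len2 == 0) next
      t0 <- pmin(pmax(as.vector(sweep(cen, 2, a) %*% ab) / len2, 0), 1)
      proj <- outer(t0, ab) + rep(a, each = nrow(cen))
      d2 <- pmin(d2, rowSums((cen - proj)^2))
    }
  }
  sqrt(d2)
}

# add an anchor point (e.g. the insertion point) as an extra skeleton node
# connected to its nearest node, so the curve reaches the spine base; a
# synthetic leaf extension sitting where the anchor belongs is replaced by
# the anchor itself (extensions at curved bases can point off-axis)
augment_skeleton <- function(skel, point) {
  nn <- nearest_node(skel, point)
  if (nn %in% skel$ext_nodes && nrow(skel$nodes) > 1) {
    keep <- setdiff(seq_len(nrow(skel$nodes)), nn)
    remap <- integer(nrow(skel$nodes))
    remap[keep] <- seq_along(keep)
    skel$nodes <- skel$nodes[keep, , drop = FALSE]
    ke <- skel$edges[, 1] != nn & skel$edges[, 2] != nn
    skel$edges <- matrix(remap[skel$edges[ke, , drop = FALSE]], ncol = 2)
    skel$ext_nodes <- remap[setdiff(skel$ext_nodes, nn)]
    nn <- nearest_node(skel, point)
  }
  k <- nrow(skel$nodes)
  skel$nodes <- rbind(skel$nodes, point)
  dimnames(skel$nodes) <- NULL
  skel$edges <- rbind(skel$edges, c(nn, k + 1L))
  skel$anchor_node <- k + 1L
  skel
}
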