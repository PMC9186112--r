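#' Construct a triangle mesh
#'
#' The basic container used throughout the package: a vertex matrix in
#' micrometers and a face matrix of vertex indices. Degenerate faces
#' (repeated vertex indices or zero area) are dropped with a message,
#' mirroring the slivers commonly produced by surface-reconstruction
#' pipelines.
#'
#' @param vertices numeric matrix, n x 3, coordinates in micrometers.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param drop_degenerate drop zero-area / duplicate-index faces (default TRUE).
#' @return an object of class `tri_mesh` with elements `vertices` and `faces`.
#' @export
tri_mesh <- function(vertices, faces, drop_degenerate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix of vertex indices")
  if (nrow(faces) == 0L) stop("empty mesh: no faces")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  if (drop_degenerate) {
    dup <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    areas <- face_areas_raw(vertices, faces)
    bad <- dup | areas <= .Machine$double.eps
    if (any(bad)) {
      message(sprintf("dropping %d degenerate face(s)", sum(bad)))
      faces <- faces[!bad, , drop = FALSE]
      if (nrow(faces) == 0L) stop("empty mesh: all faces degenerate")
    }
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @exportS3Method base::print
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces, %d component(s)\n",
              nrow(x$vertices), nrow(x$faces), mesh_component_count(x)))
  invisible(x)
}

face_areas_raw <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a
  v <- c - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Per-face areas, normals and centroids
#'
#' @param mesh a `tri_mesh`.
#' @return `face_areas`: numeric vector of areas (square micrometers).
#' @export
face_areas <- function(mesh) face_areas_raw(mesh$vertices, mesh$faces)

#' @rdname face_areas
#' @return `face_centroids`: m x 3 matrix of face centroids.
#' @export
face_centroids <- function(mesh) {
  (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
     mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
     mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
}

#' @rdname face_areas
#' @return `face_normals`: m x 3 matrix of unit face normals (orientation as
#'   stored; outward for meshes produced by this package).
#' @export
face_normals <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  u <- b - a
  v <- c - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n <- sqrt(rowSums(cr^2))
  n[n == 0] <- 1
  cr / n
}

# Edge table: one row per undirected edge occurrence, with the face it came
# from. Columns: v1 < v2, face.
mesh_edge_table <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  data.frame(v1 = e[, 1], v2 = e[, 2], face = rep(seq_len(nrow(f)), 3L))
}

#' Face adjacency over shared edges
#'
#' @param mesh a `tri_mesh`.
#' @return two-column integer matrix; each row is a pair of face indices that
#'   share an edge.
#' @export
face_adjacency <- function(mesh) {
  et <- mesh_edge_table(mesh)
  key <- paste(et$v1, et$v2)
  sp <- split(et$face, key)
  pairs <- lapply(sp, function(fs) {
    if (length(fs) < 2L) return(NULL)
    t(utils::combn(sort(fs), 2L))
  })
  out <- do.call(rbind, pairs)
  if (is.null(out)) out <- matrix(integer(0), ncol = 2L)
  out
}

#' Connected components of a mesh
#'
#' Faces are connected when they share an edge; isolated vertices are ignored.
#' Vertex-sharing (but not edge-sharing) faces are also treated as connected,
#' which matches the intuitive notion of a connected fragment.
#'
#' @param mesh a `tri_mesh`.
#' @return integer vector of length `nrow(faces)` giving a component id per
#'   face (1-based, contiguous).
#' @export
mesh_components <- function(mesh) {
  # union-find over vertices referenced by faces, then faces inherit the
  # component of their vertices
  n <- nrow(mesh$vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  f <- mesh$faces
  for (k in seq_len(nrow(f))) {
    a <- find(f[k, 1]); b <- find(f[k, 2]); c <- find(f[k, 3])
    parent[b] <- a
    parent[find(c)] <- find(a)
  }
  roots <- vapply(f[, 1], find, integer(1))
  as.integer(factor(roots))
}

#' @rdname mesh_components
#' @return `mesh_component_count`: number of connected components.
#' @export
mesh_component_count <- function(mesh) max(mesh_components(mesh))

#' Watertightness check
#'
#' A mesh is watertight when every edge is shared by exactly two faces.
#'
#' @param mesh a `tri_mesh`.
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  et <- mesh_edge_table(mesh)
  all(table(paste(et$v1, et$v2)) == 2L)
}

#' Boundary loops of an open mesh
#'
#' @param mesh a `tri_mesh`.
#' @return list of integer vectors; each is an ordered cycle of vertex indices
#'   along one boundary loop. Empty list for watertight meshes.
#' @export
boundary_loops <- function(mesh) {
  et <- mesh_edge_table(mesh)
  key <- paste(et$v1, et$v2)
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1L]
  if (length(bkey) == 0L) return(list())
  be <- et[match(bkey, key), c("v1", "v2")]
  # order edges into loops
  adj <- split(c(be$v2, be$v1), c(be$v1, be$v2))
  used <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  loops <- list()
  for (i in seq_len(nrow(be))) {
    k0 <- ekey(be$v1[i], be$v2[i])
    if (!is.null(used[[k0]])) next
    loop <- c(be$v1[i], be$v2[i])
    used[[k0]] <- TRUE
    repeat {
      cur <- loop[length(loop)]
      nxts <- adj[[as.character(cur)]]
      nxt <- NA_integer_
      for (cand in nxts) {
        if (is.null(used[[ekey(cur, cand)]])) { nxt <- cand; break }
      }
      if (is.na(nxt)) break
      used[[ekey(cur, nxt)]] <- TRUE
      if (nxt == loop[1]) break
      loop <- c(loop, nxt)
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Cap boundary loops with centroid fans
#'
#' Each boundary loop is triangulated by a fan to the loop centroid, producing
#' a closed surface suitable for signed-volume computation and interior ray
#' casting. The orientation of each cap triangle is chosen to match the
#' winding of the boundary edge it covers, so a consistently oriented open
#' mesh stays consistently oriented.
#'
#' @param mesh a `tri_mesh`.
#' @return list with `mesh` (the capped `tri_mesh`) and `added_faces`
#'   (indices of cap faces in the new mesh).
#' @export
cap_holes <- function(mesh) {
  loops <- boundary_loops(mesh)
  if (length(loops) == 0L)
    return(list(mesh = mesh, added_faces = integer(0)))
  v <- mesh$vertices
  f <- mesh$faces
  # directed boundary edges as they appear in faces (to preserve winding)
  dir_edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  dkey <- paste(dir_edges[, 1], dir_edges[, 2])
  newf <- list()
  for (loop in loops) {
    cen <- colMeans(v[loop, , drop = FALSE])
    v <- rbind(v, cen)
    ci <- nrow(v)
    m <- length(loop)
    for (j in seq_len(m)) {
      a <- loop[j]
      b <- loop[if (j == m) 1L else j + 1L]
      # the face owning directed edge (a,b) or (b,a); cap must use opposite
      # direction of the existing directed edge
      if (paste(a, b) %in% dkey) {
        newf[[length(newf) + 1L]] <- c(b, a, ci)
      } else {
        newf[[length(newf) + 1L]] <- c(a, b, ci)
      }
    }
  }
  addf <- do.call(rbind, newf)
  out <- structure(list(vertices = v,
                        faces = rbind(f, addf)),
                   class = "tri_mesh")
  list(mesh = out,
       added_faces = seq.int(nrow(f) + 1L, nrow(f) + nrow(addf)))
}

#' Signed volume of a closed mesh
#'
#' Divergence-theorem volume: the sum of signed tetrahedron volumes spanned by
#' the origin and each face. Positive for consistently outward-oriented
#' surfaces.
#'
#' @param mesh a `tri_mesh` (should be closed; see [cap_holes()]).
#' @return volume in cubic micrometers (signed).
#' @export
signed_volume <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
        a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
        a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Total surface area
#'
#' @param mesh a `tri_mesh`.
#' @return area in square micrometers.
#' @export
surface_area <- function(mesh) sum(face_areas(mesh))

#' Extract a face subset as a standalone mesh
#'
#' Unreferenced vertices are removed and faces reindexed.
#'
#' @param mesh a `tri_mesh`.
#' @param face_idx integer vector of face indices to keep.
#' @return a `tri_mesh`.
#' @export
submesh <- function(mesh, face_idx) {
  f <- mesh$faces[face_idx, , drop = FALSE]
  keep <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[keep] <- seq_along(keep)
  structure(list(vertices = mesh$vertices[keep, , drop = FALSE],
                 faces = matrix(remap[f], ncol = 3L)),
            class = "tri_mesh")
}

# connected components (vertex-sharing) of a subset of faces;
# returns an integer membership vector along face_idx
face_components_vertexwise <- function(mesh, face_idx) {
  f <- mesh$faces[face_idx, , drop = FALSE]
  keep <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[keep] <- seq_along(keep)
  f2 <- matrix(remap[f], ncol = 3L)
  n <- length(keep)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(f2))) {
    a <- find(f2[k, 1])
    parent[find(f2[k, 2])] <- a
    parent[find(f2[k, 3])] <- find(a)
  }
  roots <- vapply(f2[, 1], find, integer(1))
  as.integer(factor(roots))
}

# merge two meshes into one (no welding)
merge_meshes <- function(a, b) {
  off <- nrow(a$vertices)
  structure(list(vertices = rbind(a$vertices, b$vertices),
                 faces = rbind(a$faces, b$faces + off)),
            class = "tri_mesh")
}
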