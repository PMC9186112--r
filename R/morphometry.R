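#' Head volume and area of a separated spine
#'
#' The head submesh is extracted from the labeling, its boundary loop capped
#' with a centroid fan, and the volume computed by the divergence theorem.
#' Area is the closed (capped) head surface area.
#'
#' @param spine a [spine_mesh()].
#' @param labels a separable `head_neck_labels` from [separate()].
#' @return `head_volume`: volume in cubic micrometers.
#' @export
head_volume <- function(spine, labels) {
  hm <- head_closed_mesh(spine, labels)
  v <- signed_volume(hm)
  if (v < 0) v <- -v
  if (v <= 0) stop("head submesh has no enclosed volume")
  v
}

#' @rdname head_volume
#' @return `head_area`: area in square micrometers (cap included).
#' @export
head_area <- function(spine, labels) surface_area(head_closed_mesh(spine, labels))

head_closed_mesh <- function(spine, labels) {
  if (!isTRUE(labels$separable)) stop("labels are not separable")
  sub <- submesh(spine$mesh, which(labels$labels == "head"))
  cap_holes(sub)$mesh
}

#' Sphericity of the spine head
#'
#' `pi^(1/3) * (6 V)^(2/3) / A`: 1 for a perfect sphere, smaller otherwise;
#' scale-invariant.
#'
#' @param V head volume (cubic micrometers), positive.
#' @param A head surface area (square micrometers), positive.
#' @return dimensionless sphericity.
#' @export
sphericity <- function(V, A) {
  if (any(V <= 0) || any(A <= 0)) stop("V and A must be positive")
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

#' Neck length along the skeleton
#'
#' Arc length along the curve skeleton from the node nearest the insertion
#' point to the node nearest the head/neck boundary ring, plus the offsets
#' from the insertion point to the first node and from the last node to the
#' boundary ring centroid. Falls back (with attribute `flagged`) to the
#' Euclidean insertion-to-boundary distance when the skeleton is collapsed.
#'
#' @param spine a [spine_mesh()].
#' @param labels separable `head_neck_labels`.
#' @param skeleton optionally, the `spine_skeleton` (defaults to the one in
#'   `labels`).
#' @return neck length in micrometers.
#' @export
neck_length <- function(spine, labels, skeleton = labels$skeleton) {
  if (!isTRUE(labels$separable)) stop("labels are not separable")
  bverts <- boundary_ring_vertices(spine$mesh, labels)
  bcen <- colMeans(spine$mesh$vertices[bverts, , drop = FALSE])
  ip <- spine$insertion_point
  if (is.null(skeleton) || skeleton$collapsed || nrow(skeleton$edges) == 0) {
    out <- sqrt(sum((bcen - ip)^2))
    attr(out, "flagged") <- TRUE
    return(out)
  }
  n_from <- nearest_node(skeleton, ip)
  gr <- skeleton_graph(skeleton)
  D <- igraph::distances(gr, v = n_from)[1, ]
  # target: the point of the skeleton curve closest to the boundary-ring
  # centroid (projected onto edges, not just nodes), measured by arc from
  # the anchor
  best_d <- Inf
  best_arc <- NA_real_
  for (k in seq_len(nrow(skeleton$edges))) {
    u <- skeleton$edges[k, 1]; v <- skeleton$edges[k, 2]
    a <- skeleton$nodes[u, ]; b <- skeleton$nodes[v, ]
    ab <- b - a
    len <- sqrt(sum(ab^2))
    if (len == 0) next
    t0 <- min(max(sum((bcen - a) * ab) / len^2, 0), 1)
    p <- a + t0 * ab
    dd <- sqrt(sum((bcen - p)^2))
    if (dd < best_d) {
      best_d <- dd
      best_arc <- min(D[u] + t0 * len, D[v] + (1 - t0) * len)
    }
  }
  if (!is.finite(best_arc)) {
    out <- sqrt(sum((bcen - ip)^2))
    attr(out, "flagged") <- TRUE
    return(out)
  }
  best_arc + sqrt(sum((skeleton$nodes[n_from, ] - ip)^2))
}

# vertices on the head/neck interface: referenced by faces of both labels
# (for a vertex-welded repair cylinder the interface is a single vertex)
boundary_ring_vertices <- function(mesh, labels) {
  hv <- unique(as.vector(mesh$faces[labels$labels == "head", ]))
  nv <- unique(as.vector(mesh$faces[labels$labels == "neck", ]))
  vv <- intersect(hv, nv)
  if (length(vv) == 0) stop("labeling has no boundary")
  vv
}

#' Neck diameter from the shape diameter function
#'
#' Median SDF over neck-labeled faces, reported in nanometers. Defined only
#' for unrepaired (group A) spines: the repair cylinder radius is an
#' arbitrary constant, so diameters of repaired spines are a policy error.
#' Values under the ~200 nm light-microscopy resolution proxy are flagged
#' `sub_resolution` rather than censored.
#'
#' @param spine a [spine_mesh()].
#' @param labels separable `head_neck_labels`.
#' @param features data.frame with per-face `sdf` (defaults to the one
#'   computed during separation).
#' @param repaired was this spine repaired? (`TRUE` raises the policy error.)
#' @return diameter in nanometers, attribute `sub_resolution`.
#' @export
neck_diameter <- function(spine, labels, features = labels$features,
                          repaired = FALSE) {
  if (isTRUE(repaired))
    stop("neck diameter is not measured on repaired spines")
  if (!isTRUE(labels$separable)) stop("labels are not separable")
  d_um <- stats::median(features$sdf[labels$labels == "neck"])
  out <- 1000 * d_um
  attr(out, "sub_resolution") <- out < 200
  out
}

#' Spine length along the skeleton
#'
#' Distance from the insertion point to its nearest skeleton node plus the
#' longest skeleton arc from there (the skeleton's leaves are extended to
#' the tips of the mesh, so the arc reaches the end of the spine). Falls
#' back to the maximal insertion-to-vertex distance (flagged) when the
#' skeleton is collapsed.
#'
#' @param spine a [spine_mesh()].
#' @param skeleton a `spine_skeleton` for the spine's mesh.
#' @return spine length in micrometers.
#' @export
spine_length <- function(spine, skeleton) {
  ip <- spine$insertion_point
  V <- spine$mesh$vertices
  if (skeleton$collapsed || nrow(skeleton$edges) == 0) {
    out <- max(sqrt(colSums((t(V) - ip)^2)))
    attr(out, "flagged") <- TRUE
    return(out)
  }
  n_from <- nearest_node(skeleton, ip)
  gr <- skeleton_graph(skeleton)
  d <- igraph::distances(gr, v = n_from)[1, ]
  d[!is.finite(d)] <- -Inf
  arc <- max(d)
  sqrt(sum((skeleton$nodes[n_from, ] - ip)^2)) + arc
}

#' Total spine volume
#'
#' Divergence-theorem volume of the capped spine mesh; the orientation is
#' repaired (sign flip) once if the signed volume comes out negative.
#'
#' @param spine a [spine_mesh()] (single component).
#' @return volume in cubic micrometers.
#' @export
spine_volume <- function(spine) {
  m <- cap_holes(spine$mesh)$mesh
  v <- signed_volume(m)
  if (v < 0) v <- -v
  if (v == 0) stop("mesh encloses no volume")
  v
}

#' Measure one spine end to end
#'
#' Computes the full morphometric record for a (native or repaired)
#' single-component spine: head volume/area and sphericity, neck length,
#' neck diameter (group A only), spine length and volume. Neck fields are
#' absent (NA) for non-separable spines; neck diameter is absent for
#' repaired spines by policy.
#'
#' @param spine a [spine_mesh()].
#' @param group completeness group (`"A"`/`"B"` decided here from the
#'   separation outcome when `"pending"`).
#' @param repaired logical; TRUE for group C/D spines after repair.
#' @param operations character vector of repair operations (provenance).
#' @param params a [segmentation_params()].
#' @return one-row data.frame (see [write_records()] for columns), plus
#'   attribute `labels` with the `head_neck_labels`.
#' @export
measure_spine <- function(spine, group = "pending", repaired = FALSE,
                          operations = character(0),
                          params = segmentation_params()) {
  labs <- separate(spine, params)
  skel <- labs$skeleton
  if (group == "pending") group <- if (labs$separable) "A" else "B"
  rec <- data.frame(spine_id = spine$spine_id, group = group,
                    repaired = repaired,
                    head_volume_um3 = NA_real_, head_area_um2 = NA_real_,
                    sphericity = NA_real_, neck_length_um = NA_real_,
                    neck_diameter_nm = NA_real_,
                    spine_length_um = NA_real_, spine_volume_um3 = NA_real_,
                    species = spine$species, compartment = spine$compartment,
                    subject_id = spine$subject_id,
                    dendrite_id = spine$dendrite_id,
                    stringsAsFactors = FALSE)
  rec$spine_volume_um3 <- spine_volume(spine)
  rec$spine_length_um <- as.numeric(spine_length(spine, skel))
  if (labs$separable) {
    V <- head_volume(spine, labs)
    A <- head_area(spine, labs)
    rec$head_volume_um3 <- V
    rec$head_area_um2 <- A
    rec$sphericity <- sphericity(V, A)
    rec$neck_length_um <- as.numeric(neck_length(spine, labs))
    if (!repaired)
      rec$neck_diameter_nm <- as.numeric(neck_diameter(spine, labs))
  }
  attr(rec, "labels") <- labs
  rec
}
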