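#' Load a spine mesh from OBJ or ASCII PLY
#'
#' Reads vertex and triangular-face data; normals, texture coordinates and
#' materials are ignored. Polygonal faces are fan-triangulated. Multiple
#' connected components are preserved in one mesh. Coordinates are multiplied
#' by `unit_scale` so that downstream code always works in micrometers.
#'
#' @param path OBJ (`.obj`) or ASCII PLY (`.ply`) file.
#' @param unit_scale positive scale applied to all coordinates
#'   (e.g. `1e-3` for nm-unit files).
#' @return a [tri_mesh()].
#' @export
load_spine_mesh <- function(path, unit_scale = 1) {
  if (!is.numeric(unit_scale) || length(unit_scale) != 1L || unit_scale <= 0)
    stop("unit_scale must be a positive scalar")
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
              obj = read_obj(path),
              ply = read_ply_ascii(path),
              stop("unsupported mesh format: .", ext))
  m$vertices <- m$vertices * unit_scale
  m
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(flines) == 0L) stop("empty mesh: no faces in ", path)
  vparts <- strsplit(sub("^v\\s+", "", vlines), "\\s+")
  verts <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3)))
  fparts <- strsplit(sub("^f\\s+", "", flines), "\\s+")
  tris <- list()
  nv <- nrow(verts)
  for (p in fparts) {
    idx <- as.integer(vapply(strsplit(p, "/"), `[[`, "", 1L))
    idx[idx < 0] <- nv + 1L + idx[idx < 0]  # negative indices count from end
    if (length(idx) < 3L) next
    for (k in seq_len(length(idx) - 2L))
      tris[[length(tris) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
  }
  tri_mesh(verts, do.call(rbind, tris))
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  fmt <- grep("^format", lines, value = TRUE)[1]
  if (!grepl("ascii", fmt))
    stop("binary PLY is not supported; convert to ASCII PLY or OBJ")
  endh <- which(trimws(lines) == "end_header")[1]
  header <- lines[seq_len(endh)]
  el <- grep("^element", header)
  counts <- list()
  order <- character(0)
  for (i in el) {
    p <- strsplit(trimws(header[i]), "\\s+")[[1]]
    counts[[p[2]]] <- as.integer(p[3])
    order <- c(order, p[2])
  }
  if (is.null(counts$vertex) || is.null(counts$face))
    stop("PLY must declare vertex and face elements")
  body <- lines[-seq_len(endh)]
  body <- body[nzchar(trimws(body))]
  pos <- 0L
  verts <- NULL; tris <- list()
  for (name in order) {
    n <- counts[[name]]
    chunk <- body[pos + seq_len(n)]
    pos <- pos + n
    if (name == "vertex") {
      vp <- strsplit(trimws(chunk), "\\s+")
      verts <- t(vapply(vp, function(p) as.numeric(p[1:3]), numeric(3)))
    } else if (name == "face") {
      fp <- strsplit(trimws(chunk), "\\s+")
      for (p in fp) {
        k <- as.integer(p[1])
        idx <- as.integer(p[2:(1 + k)]) + 1L  # PLY is 0-based
        for (j in seq_len(k - 2L))
          tris[[length(tris) + 1L]] <- idx[c(1L, j + 1L, j + 2L)]
      }
    }
  }
  if (length(tris) == 0L) stop("empty mesh: no faces in ", path)
  tri_mesh(verts, do.call(rbind, tris))
}

#' Write a mesh as Wavefront OBJ
#'
#' @param mesh a `tri_mesh`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

#' Axial scale correction
#'
#' Confocal stacks are distorted along the optical axis; meshes derived from
#' them are corrected by multiplying every z-coordinate by a constant factor
#' (0.84 for the datasets this package targets) before any measurement.
#'
#' @param mesh a `tri_mesh`.
#' @param factor positive scalar applied to the z-dimension.
#' @return the corrected `tri_mesh`.
#' @export
apply_z_correction <- function(mesh, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    stop("z-correction factor must be a positive scalar")
  mesh$vertices[, 3] <- mesh$vertices[, 3] * factor
  mesh
}

#' Build a spine descriptor
#'
#' Bundles a mesh with its dendritic-shaft insertion point and metadata; the
#' unit of analysis for the whole pipeline.
#'
#' @param mesh a `tri_mesh` (micrometers).
#' @param insertion_point numeric length-3, where the neck meets the shaft.
#' @param species `"human"` or `"mouse"`.
#' @param compartment `"apical"` or `"basal"`.
#' @param spine_id,subject_id,dendrite_id identifier strings.
#' @return an object of class `spine_mesh`.
#' @export
spine_mesh <- function(mesh, insertion_point, species = "human",
                       compartment = "basal", spine_id = "spine",
                       subject_id = NA_character_,
                       dendrite_id = NA_character_) {
  stopifnot(inherits(mesh, "tri_mesh"))
  insertion_point <- as.numeric(insertion_point)
  if (length(insertion_point) != 3L || !all(is.finite(insertion_point)))
    stop("insertion_point must be a finite 3D point")
  species <- match.arg(species, c("human", "mouse"))
  compartment <- match.arg(compartment, c("apical", "basal"))
  structure(list(mesh = mesh, insertion_point = insertion_point,
                 species = species, compartment = compartment,
                 spine_id = as.character(spine_id),
                 subject_id = as.character(subject_id),
                 dendrite_id = as.character(dendrite_id)),
            class = "spine_mesh")
}

#' @exportS3Method base::print
print.spine_mesh <- function(x, ...) {
  cat(sprintf("spine_mesh '%s' (%s, %s): %d faces, %d component(s)\n",
              x$spine_id, x$species, x$compartment, nrow(x$mesh$faces),
              mesh_component_count(x$mesh)))
  invisible(x)
}

#' Load a dataset manifest
#'
#' A manifest is one JSON (or YAML, when the `yaml` package is installed)
#' document describing a spine dataset:
#' \preformatted{
#' {"unit_scale": 1.0, "z_correction": 0.84,
#'  "spines": [{"id": "s1", "path": "s1.obj",
#'              "insertion_point": [0,0,0],
#'              "species": "human", "compartment": "basal",
#'              "subject": "h40", "dendrite": "d1"}, ...]}
#' }
#' Relative mesh paths are resolved against the manifest's directory. The
#' z-correction is a dataset-level acquisition setting, applied exactly once
#' at load time by [load_dataset()].
#'
#' @param path manifest file (`.json`, `.yaml`/`.yml`).
#' @return a list of class `dataset_manifest` with `spines` (list of entry
#'   lists), `unit_scale`, `z_correction`, `base_dir`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML manifests need the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  if (is.null(doc$spines) || length(doc$spines) == 0L)
    stop("manifest has no 'spines' entries")
  unit_scale <- if (is.null(doc$unit_scale)) 1 else as.numeric(doc$unit_scale)
  if (!is.finite(unit_scale) || unit_scale <= 0)
    stop("manifest unit_scale must be positive")
  zc <- if (is.null(doc$z_correction)) 1 else as.numeric(doc$z_correction)
  if (!is.finite(zc) || zc <= 0) stop("manifest z_correction must be positive")
  ids <- character(0)
  problems <- character(0)
  for (e in doc$spines) {
    id <- if (is.null(e$id)) "<missing id>" else as.character(e$id)
    if (is.null(e$path))
      problems <- c(problems, sprintf("spine '%s': missing path", id))
    ip <- e$insertion_point
    if (is.null(ip) || length(unlist(ip)) != 3L ||
        !all(is.finite(as.numeric(unlist(ip)))))
      problems <- c(problems,
                    sprintf("spine '%s': missing or invalid insertion_point", id))
    ids <- c(ids, id)
  }
  dups <- unique(ids[duplicated(ids)])
  if (length(dups))
    problems <- c(problems,
                  sprintf("duplicate spine_id: %s", paste(dups, collapse = ", ")))
  if (length(problems))
    stop("invalid manifest:\n  ", paste(problems, collapse = "\n  "))
  structure(list(spines = doc$spines, unit_scale = unit_scale,
                 z_correction = zc,
                 base_dir = dirname(normalizePath(path))),
            class = "dataset_manifest")
}

#' Load all spines described by a manifest
#'
#' Applies the manifest's unit scale and z-correction to every mesh
#' (insertion points are scaled/corrected identically so geometry and anchor
#' stay consistent).
#'
#' @param manifest a `dataset_manifest` from [load_manifest()], or a path.
#' @return list of [spine_mesh()] objects.
#' @export
load_dataset <- function(manifest) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  lapply(manifest$spines, function(e) {
    p <- e$path
    if (!file.exists(p)) p <- file.path(manifest$base_dir, e$path)
    m <- load_spine_mesh(p, unit_scale = manifest$unit_scale)
    m <- apply_z_correction(m, manifest$z_correction)
    ip <- as.numeric(unlist(e$insertion_point)) * manifest$unit_scale
    ip[3] <- ip[3] * manifest$z_correction
    spine_mesh(m, ip,
               species = if (is.null(e$species)) "human" else e$species,
               compartment = if (is.null(e$compartment)) "basal" else e$compartment,
               spine_id = e$id,
               subject_id = if (is.null(e$subject)) NA else e$subject,
               dendrite_id = if (is.null(e$dendrite)) NA else e$dendrite)
  })
}

# Fixed column order of the morphometry table; units encoded in names.
morphometry_columns <- c("spine_id", "group", "repaired",
                         "head_volume_um3", "head_area_um2", "sphericity",
                         "neck_length_um", "neck_diameter_nm",
                         "spine_length_um", "spine_volume_um3",
                         "species", "compartment", "subject_id", "dendrite_id")

#' Write / read a morphometry table
#'
#' CSV with a `#`-prefixed header comment documenting units. Missing values
#' (e.g. neck diameter of repaired spines) are written as empty cells, never
#' as zeros. Numeric values round-trip at 9 significant digits.
#'
#' @param records data.frame of morphometry records (see
#'   [measure_spine()]) or a list of such single-row data.frames.
#' @param path output CSV path.
#' @return `path` invisibly (`write_records`); data.frame (`read_records`).
#' @export
write_records <- function(records, path) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame")
  miss <- setdiff(morphometry_columns, names(records))
  for (m in miss) records[[m]] <- NA
  records <- records[, morphometry_columns]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# spinemorph morphometry table",
               "# units: volumes um^3, areas um^2, lengths um, neck diameter nm",
               "# empty cells denote values not measurable for that spine"),
             con)
  num <- vapply(records, is.numeric, logical(1))
  out <- records
  out[num] <- lapply(records[num], function(x) {
    ifelse(is.na(x), "", sprintf("%.9g", x))
  })
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  numcols <- c("head_volume_um3", "head_area_um2", "sphericity",
               "neck_length_um", "neck_diameter_nm", "spine_length_um",
               "spine_volume_um3")
  for (cn in intersect(numcols, names(df))) df[[cn]] <- as.numeric(df[[cn]])
  if ("repaired" %in% names(df)) df$repaired <- as.logical(df$repaired)
  df
}
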