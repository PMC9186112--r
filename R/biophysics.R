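#' Passive spine-neck resistance index
#'
#' Under the passive model the neck's electrical resistance is proportional
#' to its length over cross-sectional area, `R_neck = rho * l / (pi r^2)`
#' with `rho` the cytosolic resistivity. The index reported here is
#' `l / (pi r^2)` in reciprocal micrometers, deliberately leaving the
#' resistivity out: ratios between geometries are resistivity-free, and
#' absolute values can be anchored to a published reference measurement via
#' [absolute_resistance()].
#'
#' @param length_um neck length `l`, micrometers.
#' @param radius_um neck radius `r`, micrometers.
#' @return index in 1/micrometers.
#' @export
resistance_index <- function(length_um, radius_um) {
  if (any(length_um <= 0) || any(radius_um <= 0))
    stop("neck length and radius must be positive")
  length_um / (pi * radius_um^2)
}

#' Ratio of two neck resistances
#'
#' `resistance_index(a) / resistance_index(b)`; invariant under a common
#' rescaling of both geometries, so the unit cancels.
#'
#' @param length_a,radius_a geometry of the numerator neck (micrometers).
#' @param length_b,radius_b geometry of the denominator neck (micrometers).
#' @return dimensionless ratio.
#' @export
resistance_ratio <- function(length_a, radius_a, length_b, radius_b) {
  resistance_index(length_a, radius_a) / resistance_index(length_b, radius_b)
}

#' Absolute neck resistance from a reference measurement
#'
#' Scales a published reference resistance by the passive-model ratio of the
#' two geometries: `R = R_ref * index(g) / index(g_ref)`.
#'
#' @param length_um,radius_um geometry of the neck of interest (micrometers).
#' @param ref_length_um,ref_radius_um reference geometry (micrometers).
#' @param ref_megohm reference resistance, megaohms (> 0).
#' @return resistance in megaohms.
#' @export
absolute_resistance <- function(length_um, radius_um,
                                ref_length_um, ref_radius_um, ref_megohm) {
  if (ref_megohm <= 0) stop("reference resistance must be positive")
  ref_megohm * resistance_ratio(length_um, radius_um,
                                ref_length_um, ref_radius_um)
}

#' Per-group median neck geometry and pairwise resistance ratios
#'
#' Population-level summary in the style used to compare species: per group,
#' the median neck length and radius (radius = diameter/2, rounded to the
#' nanometer to mirror how published medians are quoted), the resistance
#' index of that median geometry, and all pairwise ratios. Only unrepaired
#' group-A records carry a neck diameter, so only they enter.
#'
#' @param records morphometry data.frame (see [write_records()]).
#' @param grouping name of the factor column to split by (e.g. "species").
#' @param median_of_geometry if TRUE (default) ratios come from the medians
#'   of length and radius (the standard convention); if FALSE, from the
#'   median of per-spine indices.
#' @return list with `groups` (data.frame) and `ratios` (data.frame).
#' @export
resistance_report <- function(records, grouping = "species",
                              median_of_geometry = TRUE) {
  ok <- records$group == "A" & !records$repaired &
    is.finite(records$neck_length_um) & is.finite(records$neck_diameter_nm)
  d <- records[ok, , drop = FALSE]
  if (nrow(d) == 0) stop("no group-A records with neck diameter")
  gs <- split(d, d[[grouping]], drop = TRUE)
  groups <- do.call(rbind, lapply(names(gs), function(g) {
    x <- gs[[g]]
    l <- stats::median(x$neck_length_um)
    r <- round(stats::median(x$neck_diameter_nm) / 2) / 1000 # nm -> um
    data.frame(group = g, n = nrow(x), median_neck_length_um = l,
               median_neck_radius_um = r,
               resistance_index = resistance_index(l, r),
               median_index = stats::median(
                 resistance_index(x$neck_length_um,
                                  x$neck_diameter_nm / 2000)),
               stringsAsFactors = FALSE)
  }))
  combs <- if (nrow(groups) >= 2) utils::combn(nrow(groups), 2) else
    matrix(integer(0), 2)
  ratios <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
    i <- combs[1, k]; j <- combs[2, k]
    rr <- if (median_of_geometry)
      groups$resistance_index[i] / groups$resistance_index[j]
    else groups$median_index[i] / groups$median_index[j]
    data.frame(a = groups$group[i], b = groups$group[j], ratio = rr,
               stringsAsFactors = FALSE)
  }))
  list(groups = groups, ratios = ratios)
}
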