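#' Define a membrane reference frame
#'
#' Fixes the convention every direction-dependent computation uses: the
#' membrane normal is an axis (default z) and the extracellular side lies at
#' positive values.  Leaflet planes delimit "bulk" solvent: waters below
#' \code{z_inner} belong to the intracellular solution, ions beyond
#' \code{z_outer} have reached the extracellular side.
#'
#' @param z_inner inner-leaflet plane (Angstrom).
#' @param z_outer outer-leaflet plane; must exceed \code{z_inner}.
#' @param normal_axis one of "x","y","z" (default "z").
#' @param extracellular_sign +1 if the extracellular side is at positive
#'   axis values (default), -1 otherwise.
#' @return object of class \code{clc_membrane}.
#' @export
membrane_frame <- function(z_inner, z_outer, normal_axis = "z",
                           extracellular_sign = 1) {
  stopifnot(normal_axis %in% c("x", "y", "z"),
            extracellular_sign %in% c(-1, 1))
  if (!(z_outer > z_inner))
    stop("z_outer must exceed z_inner under the stated sign convention")
  structure(list(z_inner = z_inner, z_outer = z_outer,
                 normal_axis = normal_axis,
                 extracellular_sign = extracellular_sign,
                 axis_index = match(normal_axis, c("x", "y", "z"))),
            class = "clc_membrane")
}

#' Declare a named atom region
#'
#' A region is resolved against a topology (and optionally a frame +
#' membrane) to a deterministic set of atom ids.  Selector components
#' combine conjunctively; all are optional.  Spatial predicates
#' (\code{z_below}, \code{z_above}, \code{sphere}) require frame
#' coordinates, and z-relative predicates require a membrane frame.
#'
#' @param name label for reporting.
#' @param residue_numbers integer vector, or NULL.
#' @param atom_names character vector, or NULL.
#' @param chain_id chain(s), or NULL.
#' @param role atom role filter ("water", "ion", ...), or NULL.
#' @param element element filter, or NULL.
#' @param z_below,z_above select atoms with membrane-axis coordinate below /
#'   above the value (Angstrom, absolute frame coordinates).
#' @param sphere list(center = c(x,y,z), radius) in Angstrom.
#' @return object of class \code{clc_region}.
#' @export
region_spec <- function(name, residue_numbers = NULL, atom_names = NULL,
                        chain_id = NULL, role = NULL, element = NULL,
                        z_below = NULL, z_above = NULL, sphere = NULL) {
  if (!is.null(sphere))
    stopifnot(length(sphere$center) == 3, sphere$radius > 0)
  structure(list(name = name, residue_numbers = residue_numbers,
                 atom_names = atom_names, chain_id = chain_id, role = role,
                 element = element, z_below = z_below, z_above = z_above,
                 sphere = sphere),
            class = "clc_region")
}

#' Resolve a region to atom ids
#'
#' Deterministic: the result is a sorted atom-id vector; an empty result is
#' legal and returned as \code{integer(0)}.
#'
#' @param region \code{clc_region}.
#' @param topology \code{clc_topology}.
#' @param frame n_atoms x 3 coordinate matrix; required when the region has
#'   spatial predicates.
#' @param membrane \code{clc_membrane}; required for z predicates.
#' @return sorted integer vector of atom ids.
#' @export
resolve_region <- function(region, topology, frame = NULL, membrane = NULL) {
  stopifnot(inherits(region, "clc_region"), inherits(topology, "clc_topology"))
  a <- topology$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(region$residue_numbers))
    keep <- keep & a$residue_number %in% region$residue_numbers
  if (!is.null(region$atom_names))
    keep <- keep & a$atom_name %in% region$atom_names
  if (!is.null(region$chain_id))
    keep <- keep & a$chain_id %in% region$chain_id
  if (!is.null(region$role))
    keep <- keep & a$role %in% region$role
  if (!is.null(region$element))
    keep <- keep & a$element %in% region$element
  spatial <- !is.null(region$z_below) || !is.null(region$z_above) ||
    !is.null(region$sphere)
  if (spatial) {
    if (is.null(frame))
      stop("region '", region$name, "' has spatial predicates: frame required")
    if ((!is.null(region$z_below) || !is.null(region$z_above)) &&
        is.null(membrane))
      stop("region '", region$name,
           "' has z predicates: membrane frame required")
    if (!is.null(region$z_below))
      keep <- keep & frame[, membrane$axis_index] < region$z_below
    if (!is.null(region$z_above))
      keep <- keep & frame[, membrane$axis_index] > region$z_above
    if (!is.null(region$sphere)) {
      d2 <- (frame[, 1] - region$sphere$center[1])^2 +
        (frame[, 2] - region$sphere$center[2])^2 +
        (frame[, 3] - region$sphere$center[3])^2
      keep <- keep & d2 <= region$sphere$radius^2
    }
  }
  sort(a$atom_id[keep])
}
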