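#' Construct a density map
#'
#' @param values 3-D numeric array indexed [x, y, z] (map units).
#' @param voxel_size voxel edge lengths, Angstrom (length 1 or 3).
#' @param origin Cartesian position of the first voxel center, Angstrom.
#' @return object of class \code{clc_density_map}.
#' @export
density_map <- function(values, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(length(dim(values)) == 3, all(dim(values) >= 1))
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0),
            length(origin) == 3)
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "clc_density_map")
}

#' @export
print.clc_density_map <- function(x, ...) {
  cat("<clc_density_map> ", paste(dim(x$values), collapse = " x "),
      " voxels, voxel ", paste(signif(x$voxel_size, 4), collapse = "/"),
      " A, origin (", paste(signif(x$origin, 4), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Whole-map statistics
#'
#' Mean and population standard deviation over every voxel of the map (no
#' solvent mask), the normalization that converts a raw density into a
#' z-score; an optional logical mask restricts the statistics.
#'
#' @param map \code{clc_density_map}.
#' @param mask optional logical array of the map's dimensions.
#' @return list(mean, sd, n_voxels).
#' @export
map_statistics <- function(map, mask = NULL) {
  v <- map$values
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(v)))
    v <- v[mask]
  }
  n <- length(v)
  m <- mean(v)
  s <- sqrt(sum((v - m)^2) / n)     # population SD
  list(mean = m, sd = s, n_voxels = n)
}

#' Map z-score at a Cartesian coordinate
#'
#' The density value at the coordinate (trilinear interpolation by
#' default), expressed as the number of whole-map standard deviations above
#' the whole-map mean: \eqn{Z = (\rho - \mu) / \sigma}.  This normalized
#' contour level lets ion-site signals be compared across maps whose
#' absolute intensity scales differ.
#'
#' @param map \code{clc_density_map}.
#' @param coordinate Cartesian (x, y, z), Angstrom; must fall inside the
#'   voxel-center bounding box.
#' @param stats optional precomputed [map_statistics()] result.
#' @param interpolation "trilinear" (default) or "nearest".
#' @return z-score ("sigma"), a bare number.
#' @export
zscore_at <- function(map, coordinate, stats = NULL,
                      interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (is.null(stats)) stats <- map_statistics(map)
  if (stats$sd == 0)
    stop("degenerate map: zero standard deviation, z-score undefined")
  g <- (coordinate - map$origin) / map$voxel_size   # fractional voxel index
  dims <- dim(map$values)
  if (any(g < 0) || any(g > dims - 1))
    stop("coordinate outside map bounds")
  if (interpolation == "nearest") {
    idx <- pmin(pmax(round(g), 0), dims - 1) + 1
    val <- map$values[idx[1], idx[2], idx[3]]
  } else {
    i0 <- pmin(floor(g), dims - 2); i0 <- pmax(i0, 0)
    f <- g - i0
    i0 <- i0 + 1                                    # 1-based corner
    val <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx == 1) f[1] else 1 - f[1]) *
        (if (dy == 1) f[2] else 1 - f[2]) *
        (if (dz == 1) f[3] else 1 - f[3])
      if (w > 0)
        val <- val + w * map$values[i0[1] + dx, i0[2] + dy, i0[3] + dz]
    }
  }
  (val - stats$mean) / stats$sd
}

#' Read an MRC/CCP4 2014 density map
#'
#' Minimal reader for mode-2 (float32) maps.  Axis order is taken from the
#' MAPC/MAPR/MAPS header words and permuted to x/y/z; the origin comes from
#' the ORIGIN header record when set, else from NXSTART/NYSTART/NZSTART
#' times the voxel size.
#'
#' @param path MRC/CCP4 file.
#' @return \code{clc_density_map}.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  nxyz <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("unsupported MRC mode ", mode, " (only mode 2)")
  nstart <- ri(3)
  mxyz <- ri(3)
  cella <- rf(3)
  rf(3)                 # cell angles, assumed 90
  mapcrs <- ri(3)
  rf(3)                 # dmin dmax dmean
  ri(2)                 # ispg, nsymbt
  ri(25)                # extra
  origin <- rf(3)
  map_tag <- readChar(con, 4, useBytes = TRUE)
  ri(1)                 # machst
  rf(1)                 # rms
  ri(1)                 # nlabl
  readBin(con, "raw", 800)
  if (!identical(substr(map_tag, 1, 3), "MAP"))
    warning("MRC 'MAP ' tag missing; attempting to read anyway")
  nv <- prod(nxyz)
  vals <- readBin(con, "numeric", nv, size = 4, endian = "little")
  if (length(vals) < nv) stop("truncated MRC data block")
  arr <- array(vals, dim = nxyz)   # [col, row, sec]
  # permute columns/rows/sections onto x/y/z
  perm <- order(mapcrs)            # position of x,y,z among (c,r,s)
  arr <- aperm(arr, perm)
  voxel <- (cella / mxyz)[1:3]
  nstart_xyz <- nstart[perm]
  if (all(origin == 0)) origin <- nstart_xyz * voxel
  density_map(arr, voxel, origin)
}

#' Write a density map as MRC/CCP4 2014 (mode 2)
#'
#' @param map \code{clc_density_map}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_mrc <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  dims <- dim(map$values)
  st <- map_statistics(map)
  wi(dims)                       # nx ny nz
  wi(2)                          # mode 2 float32
  wi(c(0, 0, 0))                 # nstart
  wi(dims)                       # mx my mz
  wf(dims * map$voxel_size)      # cell a b c
  wf(c(90, 90, 90))
  wi(c(1, 2, 3))                 # mapc mapr maps
  wf(c(min(map$values), max(map$values), st$mean))
  wi(c(1, 0))                    # ispg, nsymbt
  wi(rep(0, 25))
  wf(map$origin)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)   # machst little-endian
  wf(st$sd)
  wi(0)                          # nlabl
  writeBin(raw(800), con)
  writeBin(as.numeric(map$values), con, size = 4, endian = "little")
  invisible(path)
}
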