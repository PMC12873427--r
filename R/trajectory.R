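#' Construct a trajectory
#'
#' @param topology \code{clc_topology}.
#' @param coords numeric array n_frames x n_atoms x 3 (Angstrom).
#' @param frame_interval_ns spacing between saved frames in ns.  Production
#'   trajectories analysed here were saved every 200 ps, so the default is
#'   0.2 ns.
#' @param box optional n_frames x 3 matrix of orthorhombic box lengths
#'   (Angstrom) enabling minimum-image distances.
#' @return object of class \code{clc_trajectory}.
#' @export
trajectory <- function(topology, coords, frame_interval_ns = 0.2, box = NULL) {
  stopifnot(inherits(topology, "clc_topology"))
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("coords must be an n_frames x n_atoms x 3 array")
  if (dim(coords)[2] != nrow(topology$atoms))
    stop("atom count mismatch: coords have ", dim(coords)[2],
         " atoms, topology has ", nrow(topology$atoms))
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (!is.numeric(frame_interval_ns) || frame_interval_ns <= 0)
    stop("frame_interval_ns must be positive")
  if (!is.null(box)) {
    box <- rbind(box)
    if (nrow(box) == 1) box <- box[rep(1, dim(coords)[1]), , drop = FALSE]
    stopifnot(nrow(box) == dim(coords)[1], ncol(box) == 3, all(box > 0))
  }
  structure(list(topology = topology, coords = coords,
                 frame_interval_ns = frame_interval_ns, box = box),
            class = "clc_trajectory")
}

#' @export
print.clc_trajectory <- function(x, ...) {
  cat("<clc_trajectory> ", n_frames(x), " frames x ", n_atoms(x),
      " atoms, dt = ", x$frame_interval_ns, " ns, duration = ",
      duration_ns(x), " ns\n", sep = "")
  invisible(x)
}

#' @rdname trajectory
#' @param x a \code{clc_trajectory}
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' Trajectory duration in nanoseconds (n_frames x frame interval)
#' @param x a \code{clc_trajectory}
#' @return duration in ns
#' @export
duration_ns <- function(x) n_frames(x) * x$frame_interval_ns

#' Extract one frame's coordinates
#' @param traj \code{clc_trajectory}
#' @param i frame index (1-based)
#' @return n_atoms x 3 matrix
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  matrix(traj$coords[i, , ], ncol = 3)
}

#' Load a trajectory from DCD or multi-model PDB files
#'
#' DCD files are read through \code{bio3d::read.dcd}; plain multi-model PDB
#' files are accepted for desk-scale fixtures.  XTC is not supported.
#' Frames from multiple files are concatenated in the order given.
#'
#' @param topology \code{clc_topology} whose atom count every frame must
#'   match (mismatch is a hard error).
#' @param paths character vector of trajectory files.
#' @param frame_interval_ns frame spacing in ns (default 0.2).
#' @param quiet suppress the frame-count message.
#' @return \code{clc_trajectory}
#' @export
load_trajectory <- function(topology, paths, frame_interval_ns = 0.2,
                            quiet = FALSE) {
  stopifnot(inherits(topology, "clc_topology"))
  nat <- nrow(topology$atoms)
  frames <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("no such file: ", p)
    ext <- tolower(tools::file_ext(p))
    if (ext == "dcd") {
      xyz <- tryCatch(bio3d::read.dcd(p, verbose = FALSE),
                      error = function(e)
                        stop("truncated or unreadable DCD '", p, "': ",
                             conditionMessage(e)))
      if (ncol(xyz) != 3 * nat)
        stop("atom count mismatch in '", p, "': file has ", ncol(xyz) / 3,
             " atoms, topology has ", nat)
      arr <- array(NA_real_, c(nrow(xyz), nat, 3))
      for (f in seq_len(nrow(xyz)))
        arr[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    } else if (ext %in% c("pdb", "ent")) {
      pdb <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
      xyz <- pdb$xyz
      if (ncol(xyz) != 3 * nat)
        stop("atom count mismatch in '", p, "': file has ", ncol(xyz) / 3,
             " atoms, topology has ", nat)
      arr <- array(NA_real_, c(nrow(xyz), nat, 3))
      for (f in seq_len(nrow(xyz)))
        arr[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    } else if (ext == "xtc") {
      stop("XTC input is not supported; convert to DCD or multi-model PDB")
    } else {
      stop("unrecognized trajectory format: ", p)
    }
    bad <- which(!apply(arr, 1, function(m) all(is.finite(m))))
    if (length(bad) > 0)
      stop("non-finite coordinates in '", p, "'; last good frame: ",
           min(bad) - 1)
    frames[[length(frames) + 1]] <- arr
  }
  nf <- sum(vapply(frames, function(a) dim(a)[1], integer(1)))
  coords <- array(NA_real_, c(nf, nat, 3))
  at <- 0
  for (a in frames) {
    coords[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  traj <- trajectory(topology, coords, frame_interval_ns)
  if (!quiet)
    message("load_trajectory: ", nf, " frames x ", nat, " atoms, duration ",
            format(duration_ns(traj)), " ns")
  traj
}

#' Write trajectory coordinates as a CHARMM-style DCD file
#'
#' Minimal single-precision DCD writer (no unit cell) used by the synthetic
#' generators so that the DCD reading path is exercised end to end.
#'
#' @param traj \code{clc_trajectory} or n_frames x n_atoms x 3 array.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_dcd <- function(traj, path) {
  coords <- if (inherits(traj, "clc_trajectory")) traj$coords else traj
  nf <- dim(coords)[1]; nat <- dim(coords)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  wrec <- function(writer) {
    # fortran unformatted record: length, payload, length
    raw_con <- rawConnection(raw(0), "wb")
    writer(raw_con)
    payload <- rawConnectionValue(raw_con)
    close(raw_con)
    writeBin(length(payload), con, size = 4, endian = "little")
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf      # number of frames
  icntrl[2] <- 1       # first step
  icntrl[3] <- 1       # step interval
  icntrl[4] <- nf
  icntrl[20] <- 24     # charmm version (no extra blocks flagged)
  wrec(function(cc) {
    writeChar("CORD", cc, nchars = 4, eos = NULL)
    writeBin(as.integer(icntrl), cc, size = 4, endian = "little")
  })
  title <- sprintf("%-80s", "clcdyn synthetic trajectory")
  wrec(function(cc) {
    writeBin(1L, cc, size = 4, endian = "little")
    writeChar(title, cc, nchars = 80, eos = NULL)
  })
  wrec(function(cc) writeBin(as.integer(nat), cc, size = 4,
                             endian = "little"))
  for (f in seq_len(nf)) {
    for (ax in 1:3) {
      writeBin(4L * nat, con, size = 4, endian = "little")
      writeBin(as.numeric(coords[f, , ax]), con, size = 4,
               endian = "little")
      writeBin(4L * nat, con, size = 4, endian = "little")
    }
  }
  invisible(path)
}
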