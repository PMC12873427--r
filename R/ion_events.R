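#' Configuration for ion-unbinding analysis
#'
#' Defaults follow the study conditions for chloride release from the anion
#' pathway: the reference is the inner-gate tyrosine (Y445) side-chain
#' hydroxyl oxygen, a smoothed Y445-to-nearest-Cl- distance above 12
#' Angstrom marks the unbound state, and smoothing uses a centered 20-ns
#' moving average.
#'
#' @param reference_region \code{clc_region} of reference atoms.
#' @param ion_region \code{clc_region} selecting the ions.
#' @param unbound_threshold Angstrom (> 0), default 12.
#' @param window_ns moving-average window, default 20.
#' @return object of class \code{clc_ion_config}.
#' @export
ion_event_config <- function(reference_region = region_spec(
                               "Y445-OH", residue_numbers = 445,
                               atom_names = "OH"),
                             ion_region = region_spec("Cl", role = "ion",
                                                      element = "Cl"),
                             unbound_threshold = 12, window_ns = 20) {
  stopifnot(unbound_threshold > 0, window_ns > 0)
  structure(list(reference_region = reference_region,
                 ion_region = ion_region,
                 unbound_threshold = unbound_threshold,
                 window_ns = window_ns),
            class = "clc_ion_config")
}

#' Construct a distance time series
#'
#' @param times_ns strictly increasing times, ns.
#' @param raw nonnegative distances, Angstrom.
#' @param label series label.
#' @param smoothed optional pre-smoothed values.
#' @return object of class \code{clc_distance_series}.
#' @export
distance_series <- function(times_ns, raw, label = "series",
                            smoothed = NULL) {
  stopifnot(length(times_ns) == length(raw), all(diff(times_ns) > 0),
            all(raw >= 0))
  structure(list(times_ns = times_ns, raw = raw, smoothed = smoothed,
                 label = label),
            class = "clc_distance_series")
}
.new_series <- distance_series

#' @export
print.clc_distance_series <- function(x, ...) {
  cat("<clc_distance_series> '", x$label, "': ", length(x$raw), " points, ",
      if (is.null(x$smoothed)) "unsmoothed" else "smoothed", "\n", sep = "")
  invisible(x)
}

#' Minimum reference-to-ion distance per frame
#'
#' For every frame, the minimum over all (reference atom, ion) pairs,
#' minimum-image aware when the trajectory carries a periodic box.
#'
#' @param traj \code{clc_trajectory}.
#' @param config \code{clc_ion_config}.
#' @param ion_id restrict to one ion atom id (default: all ions).
#' @return \code{clc_distance_series} (raw, unsmoothed).
#' @export
min_distance_series <- function(traj, config = ion_event_config(),
                                ion_id = NULL) {
  top <- traj$topology
  f1 <- frame_coords(traj, 1)
  ref <- resolve_region(config$reference_region, top, f1)
  ions <- resolve_region(config$ion_region, top, f1)
  if (!is.null(ion_id)) ions <- intersect(ions, ion_id)
  if (length(ref) == 0) stop("empty reference selection")
  if (length(ions) == 0) stop("empty ion selection")
  rref <- match(ref, top$atoms$atom_id)
  rion <- match(ions, top$atoms$atom_id)
  nf <- n_frames(traj)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    dmin <- Inf
    for (r in rref) {
      dx <- traj$coords[f, rion, 1] - traj$coords[f, r, 1]
      dy <- traj$coords[f, rion, 2] - traj$coords[f, r, 2]
      dz <- traj$coords[f, rion, 3] - traj$coords[f, r, 3]
      if (!is.null(traj$box)) {
        b <- traj$box[f, ]
        dx <- dx - b[1] * round(dx / b[1])
        dy <- dy - b[2] * round(dy / b[2])
        dz <- dz - b[3] * round(dz / b[3])
      }
      dmin <- min(dmin, sqrt(dx^2 + dy^2 + dz^2))
    }
    out[f] <- dmin
  }
  .new_series(seq_len(nf) * traj$frame_interval_ns, out,
              label = paste0(config$reference_region$name, "-to-nearest-",
                             config$ion_region$name))
}

#' Centered moving-average smoothing
#'
#' The window in frames is the nearest odd integer to
#' \code{window_ns / frame_interval}; a 20-ns window at 0.2 ns/frame is a
#' 101-frame centered window.  Windows shrink symmetrically at the series
#' edges.  A trailing (causal) mode is available.
#'
#' @param series \code{clc_distance_series}.
#' @param window_ns window size, ns; must be at least the frame interval.
#' @param mode "centered" (default) or "trailing".
#' @return the series with \code{$smoothed} filled in.
#' @export
smooth_series <- function(series, window_ns = 20,
                          mode = c("centered", "trailing")) {
  mode <- match.arg(mode)
  dt <- series$times_ns[2] - series$times_ns[1]
  if (window_ns < dt) stop("window_ns shorter than the frame interval")
  w <- round(window_ns / dt)
  if (mode == "centered") {
    if (w %% 2 == 0) w <- w + 1
    sm <- zoo::rollapply(series$raw, width = w, FUN = mean,
                         partial = TRUE, align = "center")
  } else {
    sm <- zoo::rollapply(series$raw, width = w, FUN = mean,
                         partial = TRUE, align = "right")
  }
  series$smoothed <- as.numeric(sm)
  attr(series, "window_frames") <- w
  series
}

#' Detect unbinding events from a smoothed distance series
#'
#' One event per upward crossing of the threshold: the smoothed value
#' exceeds the threshold at the crossing frame having been at or below it
#' at the previous frame.  A trajectory "shows leaving" when at least one
#' event occurred and the series ends above threshold.
#'
#' @param series smoothed \code{clc_distance_series}.
#' @param threshold Angstrom, default 12.
#' @param use_raw use the raw trace instead (sensitivity mode).
#' @return data.frame(crossing_frame, crossing_time_ns, direction) with
#'   attribute \code{"shows_leaving"}; direction is "unset" until
#'   [assign_direction()].
#' @export
detect_unbinding <- function(series, threshold = 12, use_raw = FALSE) {
  v <- if (use_raw) series$raw else series$smoothed
  if (is.null(v)) stop("series is not smoothed; call smooth_series() first")
  above <- v > threshold
  crossing <- which(above & !c(FALSE, above[-length(above)]))
  ev <- data.frame(crossing_frame = crossing,
                   crossing_time_ns = series$times_ns[crossing],
                   direction = rep("unset", length(crossing)),
                   stringsAsFactors = FALSE)
  attr(ev, "shows_leaving") <- length(crossing) > 0 && above[length(above)]
  ev
}

#' Assign the exit direction of an unbinding event
#'
#' The direction is the sign of the ion's displacement along the membrane
#' normal from the pathway-site centroid, read at the first frame (at or
#' after the crossing) where the ion's distance from the centroid exceeds
#' the bulk cutoff.  If the ion never commits to bulk before returning, the
#' direction is "indeterminate".
#'
#' @param traj \code{clc_trajectory}.
#' @param event one row of the [detect_unbinding()] frame.
#' @param membrane \code{clc_membrane} (required).
#' @param pathway_sites \code{clc_region} defining the anion-pathway
#'   centroid.
#' @param ion_id atom id of the ion.
#' @param bulk_cutoff commitment distance from the centroid, Angstrom;
#'   default 15 (must exceed the unbound threshold).
#' @return "extracellular", "intracellular" or "indeterminate".
#' @export
assign_direction <- function(traj, event, membrane, pathway_sites, ion_id,
                             bulk_cutoff = 15) {
  if (missing(membrane) || !inherits(membrane, "clc_membrane"))
    stop("membrane frame required to assign a direction")
  top <- traj$topology
  f1 <- frame_coords(traj, 1)
  sites <- resolve_region(pathway_sites, top, f1, membrane)
  if (length(sites) == 0) stop("pathway_sites resolve to no atoms")
  srows <- match(sites, top$atoms$atom_id)
  irow <- match(ion_id, top$atoms$atom_id)
  if (is.na(irow)) stop("unknown ion_id")
  ax <- membrane$axis_index
  for (f in seq(event$crossing_frame, n_frames(traj))) {
    cen <- colMeans(matrix(traj$coords[f, srows, ], ncol = 3))
    pos <- traj$coords[f, irow, ]
    if (sqrt(sum((pos - cen)^2)) >= bulk_cutoff) {
      disp <- (pos[ax] - cen[ax]) * membrane$extracellular_sign
      return(if (disp > 0) "extracellular" else "intracellular")
    }
  }
  "indeterminate"
}

#' Unbound-state occupancy fraction
#'
#' Fraction of frames whose smoothed distance exceeds the threshold; the
#' bound fraction is its exact complement.
#'
#' @inheritParams detect_unbinding
#' @return fraction in [0, 1].
#' @export
occupancy_fraction <- function(series, threshold = 12, use_raw = FALSE) {
  v <- if (use_raw) series$raw else series$smoothed
  if (is.null(v)) stop("series is not smoothed; call smooth_series() first")
  if (length(v) == 0) stop("empty series")
  mean(v > threshold)
}

#' Inner-gate separation series
#'
#' Per-frame distance between the S107 and Y445 side-chain oxygens, whose
#' mutual displacement opens the inner gate of the chloride pathway.
#'
#' @param traj \code{clc_trajectory}.
#' @param ser_region,tyr_region regions resolving to the two side-chain
#'   oxygens (defaults: residue 107 atom OG, residue 445 atom OH).
#' @param open_threshold Angstrom above which the gate is called open
#'   (interpretive default 6).
#' @return \code{clc_distance_series} with attribute \code{"open_fraction"}.
#' @export
gate_series <- function(traj,
                        ser_region = region_spec("S107-OG",
                                                 residue_numbers = 107,
                                                 atom_names = "OG"),
                        tyr_region = region_spec("Y445-OH",
                                                 residue_numbers = 445,
                                                 atom_names = "OH"),
                        open_threshold = 6) {
  top <- traj$topology
  f1 <- frame_coords(traj, 1)
  s <- resolve_region(ser_region, top, f1)
  y <- resolve_region(tyr_region, top, f1)
  missing_res <- c(if (length(s) == 0) ser_region$name,
                   if (length(y) == 0) tyr_region$name)
  if (length(missing_res) > 0)
    stop("gate residues missing from topology: ",
         paste(missing_res, collapse = ", "))
  sr <- match(s[1], top$atoms$atom_id)
  yr <- match(y[1], top$atoms$atom_id)
  d <- sqrt((traj$coords[, sr, 1] - traj$coords[, yr, 1])^2 +
              (traj$coords[, sr, 2] - traj$coords[, yr, 2])^2 +
              (traj$coords[, sr, 3] - traj$coords[, yr, 3])^2)
  ser <- .new_series(seq_len(n_frames(traj)) * traj$frame_interval_ns, d,
                     label = "S107-Y445 gate")
  attr(ser, "open_fraction") <- mean(d > open_threshold)
  attr(ser, "open_threshold") <- open_threshold
  ser
}

#' Write a distance series as TSV (time_ns, raw, smoothed)
#' @param series \code{clc_distance_series}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_series_tsv <- function(series, path) {
  df <- data.frame(time_ns = series$times_ns, raw = series$raw,
                   smoothed = if (is.null(series$smoothed)) NA
                   else series$smoothed)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
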