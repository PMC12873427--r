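# Stage orchestration over the synthetic fixtures: one structured config,
# fully serialized provenance, deterministic outputs.

.default_config <- function() {
  list(
    seed = NULL,                      # must be supplied: no silent RNG state
    stages = c("wires", "ions", "zscore", "rmsd", "hdx", "flux"),
    wires = list(n_frames = 200, chain_length = 5, wire_probability = 0.3,
                 n_decoys = 30, class_route = 2, d_da_max = 3.5,
                 angle_min_deg = 150),
    ions = list(n_runs = 4, duration_ns = 300, exit_fraction = 0.5,
                noise_sd = 0.5, unbound_threshold = 12, window_ns = 20),
    zscore = list(grid = 40, blob_peak = 8, noise_sd = 1),
    rmsd = list(n_residues = 60, displacement = 0.5),
    hdx = list(pH_ref = 6.5, pH_low = 4.5, protection = 1000,
               fd_efficiency = 0.85, noise_sd = 0.05),
    flux = list(cl_rate = 2300, h_rate = 1100, n_replicates = 6,
                n_transporters = 6.02e11))
}

.merge_config <- function(user, defaults, path = "") {
  for (key in names(user)) {
    if (!key %in% names(defaults))
      stop("unknown config key: ", paste0(path, key))
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("config key ", paste0(path, key), " must be a mapping")
      defaults[[key]] <- .merge_config(user[[key]], defaults[[key]],
                                       paste0(path, key, "."))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a run configuration
#'
#' Configs are nested lists (or a YAML file path).  Unknown keys are
#' rejected before any compute; a seed is mandatory so no randomized step
#' runs on silent RNG state.
#'
#' @param config list or path to a YAML file.
#' @return validated, fully-populated config list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  full <- .merge_config(config, .default_config())
  if (is.null(full$seed)) stop("config error: 'seed' is required")
  bad <- setdiff(full$stages, c("wires", "ions", "zscore", "rmsd", "hdx",
                                "flux"))
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  full
}

#' Run the desk-scale analysis pipeline
#'
#' Executes the selected stages on seeded synthetic fixtures, writing
#' per-stage TSV/JSON outputs, a summary report and a log of every
#' effective parameter into \code{out_dir}.  Re-running with the same
#' config produces identical report content.
#'
#' @param config list or YAML path; see [validate_config()].
#' @param out_dir output directory (created).
#' @return the summary list, invisibly; also written as summary.json.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_lines <- c(paste("clcdyn pipeline run,", "R", getRversion()),
                 paste("effective config:",
                       jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                                        null = "null")))
  summary <- list(seed = cfg$seed)
  if ("wires" %in% cfg$stages) {
    p <- cfg$wires
    fx <- make_wire_fixture(p$n_frames, p$chain_length, p$wire_probability,
                            p$n_decoys, p$class_route, seed = cfg$seed)
    res <- analyze_wires(fx$trajectory, fx$endpoints, fx$class_defs,
                         fx$membrane,
                         criteria = hbond_criteria(p$d_da_max,
                                                   p$angle_min_deg))
    utils::write.table(res$wire_table, file.path(out_dir, "wires.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    summary$wire_fraction <- res$fraction
    summary$wire_classes <- as.list(res$class_counts)
  }
  if ("ions" %in% cfg$stages) {
    p <- cfg$ions
    n_exit <- round(p$n_runs * p$exit_fraction)
    events <- list(); leaving <- 0; unbound <- numeric(0)
    dirs <- character(0)
    for (r in seq_len(p$n_runs)) {
      te <- if (r <= n_exit) p$duration_ns * 0.6 else NA
      fx <- make_ion_walk(p$duration_ns, te, "extracellular",
                          p$noise_sd, seed = cfg$seed + r)
      res <- analyze_ion_run(fx$trajectory, fx$config, fx$membrane,
                             fx$pathway_region,
                             threshold = p$unbound_threshold,
                             window_ns = p$window_ns)
      leaving <- leaving + res$shows_leaving
      unbound <- c(unbound, res$unbound_fraction)
      dirs <- c(dirs, res$events$direction)
      if (nrow(res$events) > 0)
        events[[length(events) + 1]] <- cbind(run = r, res$events)
    }
    ev <- if (length(events) > 0) do.call(rbind, events) else
      data.frame(run = integer(0), ion_id = integer(0),
                 crossing_frame = integer(0), crossing_time_ns = numeric(0),
                 direction = character(0))
    utils::write.table(ev, file.path(out_dir, "ion_events.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    summary$ion_leaving_runs <- leaving
    summary$ion_runs <- p$n_runs
    summary$ion_mean_unbound_fraction <- mean(unbound)
    summary$ion_directions <- as.list(table(dirs))
  }
  if ("zscore" %in% cfg$stages) {
    p <- cfg$zscore
    cen <- rep(p$grid / 2, 3)
    fx <- make_density_fixture(rep(p$grid, 3), 1, list(cen), 2,
                               p$blob_peak * p$noise_sd, p$noise_sd,
                               seed = cfg$seed)
    st <- map_statistics(fx$map)
    summary$zscore_at_site <- zscore_at(fx$map, cen, st)
    summary$map_mean <- st$mean
    summary$map_sd <- st$sd
  }
  if ("rmsd" %in% cfg$stages) {
    p <- cfg$rmsd
    ma <- make_helix_model(p$n_residues, seed = cfg$seed)
    mb <- perturb_model(ma, p$displacement, seed = cfg$seed + 1)
    al <- superpose_rmsd(ma, mb)
    summary$rmsd <- al$rmsd
    summary$rmsd_n_pairs <- al$n_pairs
  }
  if ("hdx" %in% cfg$stages) {
    p <- cfg$hdx
    model <- intrinsic_rate_model()
    summary$hdx_correction_factor <-
      as.numeric(correction_factor(model, p$pH_ref, p$pH_low))
    summary$hdx_matched_20s <-
      matched_timepoint(model, p$pH_ref, 20, p$pH_low)
    fx <- make_hdx_curves("pep1", list(p$protection),
                          c(p$pH_ref, p$pH_low),
                          fd_efficiency = p$fd_efficiency,
                          noise_sd = p$noise_sd, seed = cfg$seed,
                          model = model)
    dd <- differential_uptake(fx$curves[[paste("pep1", p$pH_ref)]],
                              fx$curves[[paste("pep1", p$pH_low)]], model)
    summary$hdx_mean_matched_difference <- mean(dd$difference)
  }
  if ("flux" %in% cfg$stages) {
    p <- cfg$flux
    params <- assay_params(p$n_transporters)
    reps <- lapply(seq_len(p$n_replicates), function(r) {
      fx <- make_flux_trace(p$cl_rate, p$h_rate, params,
                            seed = cfg$seed + r)
      analyze_flux_trace(fx$trace, params)
    })
    agg <- aggregate_replicates(reps)
    summary$flux_cl_rate <- agg$cl_rate
    summary$flux_h_rate <- agg$h_rate
    summary$flux_stoichiometry <- agg$stoichiometry
    summary$flux_stoichiometry_sem <- agg$stoichiometry_sem
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(summary)
}

#' Wire detection across a whole trajectory
#'
#' Per frame: H-bond graph over waters + source endpoint atoms, BFS wire
#' search, classification; then the fraction of frames with at least one
#' wire.
#'
#' @param traj \code{clc_trajectory}.
#' @param endpoints \code{clc_wire_endpoints}.
#' @param class_defs list of \code{clc_wire_class} (or NULL to skip
#'   classification).
#' @param membrane \code{clc_membrane}.
#' @param criteria \code{clc_hbond_criteria}.
#' @param method pair-search method for [detect_hbonds()].
#' @return list(per_frame_wires, fraction, wire_table, class_counts).
#' @export
analyze_wires <- function(traj, endpoints, class_defs = NULL, membrane,
                          criteria = hbond_criteria(),
                          method = "grid") {
  top <- traj$topology
  a <- top$atoms
  water_o <- a$atom_id[a$role == "water" & a$element == "O"]
  f1 <- frame_coords(traj, 1)
  src_ids <- resolve_region(endpoints$source, top, f1, membrane)
  node_set <- sort(union(water_o, src_ids))
  per_frame <- vector("list", n_frames(traj))
  rows <- list()
  for (f in seq_len(n_frames(traj))) {
    fr <- frame_coords(traj, f)
    g <- detect_hbonds(fr, top, node_set, criteria, frame_index = f,
                       method = method)
    ws <- find_wires(g, endpoints, fr, top, membrane)
    if (!is.null(class_defs)) {
      for (i in seq_along(ws))
        ws[[i]]$class_label <- classify_wire(ws[[i]], class_defs, fr, top,
                                             membrane)
    }
    per_frame[[f]] <- ws
    for (w in ws)
      rows[[length(rows) + 1]] <-
        data.frame(frame = f, class = w$class_label, n_waters = w$n_waters,
                   nodes = paste(w$nodes, collapse = ","))
  }
  wire_table <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(frame = integer(0), class = character(0),
               n_waters = integer(0), nodes = character(0))
  class_counts <- table(wire_table$class)
  list(per_frame_wires = per_frame, fraction = wire_fraction(per_frame),
       wire_table = wire_table, class_counts = class_counts)
}

#' Ion-unbinding analysis for one run
#'
#' Smoothed minimum-distance series per ion, unbinding events with
#' directions, per-run unbound occupancy and the "both ions left" flag.
#'
#' @param traj \code{clc_trajectory}.
#' @param config \code{clc_ion_config}.
#' @param membrane \code{clc_membrane}.
#' @param pathway_region \code{clc_region} for direction assignment.
#' @param threshold unbound threshold, Angstrom.
#' @param window_ns smoothing window.
#' @return list(series, events, shows_leaving, unbound_fraction).
#' @export
analyze_ion_run <- function(traj, config = ion_event_config(), membrane,
                            pathway_region, threshold = 12,
                            window_ns = 20) {
  top <- traj$topology
  f1 <- frame_coords(traj, 1)
  ions <- resolve_region(config$ion_region, top, f1)
  all_events <- list()
  per_ion_leaving <- logical(length(ions))
  pooled <- min_distance_series(traj, config)
  pooled <- smooth_series(pooled, window_ns)
  for (i in seq_along(ions)) {
    ser <- min_distance_series(traj, config, ion_id = ions[i])
    ser <- smooth_series(ser, window_ns)
    ev <- detect_unbinding(ser, threshold)
    per_ion_leaving[i] <- attr(ev, "shows_leaving")
    if (nrow(ev) > 0) {
      ev$direction <- vapply(seq_len(nrow(ev)), function(k)
        assign_direction(traj, ev[k, ], membrane, pathway_region, ions[i]),
        character(1))
    }
    if (nrow(ev) > 0) all_events[[length(all_events) + 1]] <-
        cbind(ion_id = ions[i], ev)
  }
  events <- if (length(all_events) > 0) do.call(rbind, all_events) else
    data.frame(ion_id = integer(0), crossing_frame = integer(0),
               crossing_time_ns = numeric(0), direction = character(0))
  list(series = pooled, events = events,
       shows_leaving = all(per_ion_leaving),
       unbound_fraction = occupancy_fraction(pooled, threshold))
}

#' Synthetic helical C-alpha model (and perturbations) for RMSD exercises
#'
#' \code{make_helix_model} builds an idealized all-C-alpha helix with a
#' random sequence; \code{perturb_model} adds Gaussian coordinate noise;
#' \code{rigid_transform_model} applies an exact rotation + translation
#' (RMSD-invariant by construction).
#'
#' @param n_residues residues in the helix.
#' @param seed RNG seed.
#' @param chain chain id.
#' @return \code{clc_model}
#' @export
make_helix_model <- function(n_residues = 60, seed = 1,
                                   chain = "A") {
  set.seed(seed)
  t <- seq_len(n_residues) * 100 * pi / 180
  coords <- cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * seq_len(n_residues))
  aa <- sample(c("ALA", "LEU", "SER", "VAL", "GLY", "THR", "PHE", "GLU",
                 "LYS", "ARG"), n_residues, replace = TRUE)
  at <- data.frame(atom_id = seq_len(n_residues), atom_name = "CA",
                   element = "C", residue_name = aa,
                   residue_number = seq_len(n_residues), chain_id = chain,
                   role = "protein", stringsAsFactors = FALSE)
  structure(list(topology = topology(at), coords = coords, format = "pdb"),
            class = "clc_model")
}

#' @rdname make_helix_model
#' @param model \code{clc_model} to perturb/transform
#' @param displacement_sd Gaussian displacement SD, Angstrom
#' @export
perturb_model <- function(model, displacement_sd = 0.5, seed = 1) {
  set.seed(seed)
  model$coords <- model$coords +
    matrix(stats::rnorm(length(model$coords), 0, displacement_sd),
           ncol = 3)
  model
}

#' @rdname make_helix_model
#' @param angles Euler angles, radians
#' @param translation translation vector, Angstrom
#' @export
rigid_transform_model <- function(model, angles = c(0.3, 0.5, 0.7),
                                   translation = c(5, -3, 2)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  R <- Rz %*% Ry %*% Rx
  model$coords <- t(R %*% t(model$coords)) +
    matrix(translation, nrow(model$coords), 3, byrow = TRUE)
  model
}
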