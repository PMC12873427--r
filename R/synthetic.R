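# Seeded generators producing fixtures with known ground truth for every
# pipeline stage.  Fixtures are geometric/statistical stand-ins, not
# physical simulations: coordinates carry Gaussian positional jitter, maps
# and electrode traces Gaussian additive noise, all drawn from one RNG
# stream seeded at entry (identical arguments => identical fixture).

.jit <- function(n, sd) if (sd > 0) stats::rnorm(n, 0, sd) else rep(0, n)

# water with oxygen at o; h1 points toward `toward` (unit H-O-target), h2
# roughly perpendicular
.water_coords <- function(o, toward = NULL) {
  if (is.null(toward)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  } else {
    u <- toward - o; u <- u / sqrt(sum(u^2))
  }
  # any vector perpendicular to u
  p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- p - sum(p * u) * u; v <- v / sqrt(sum(v^2))
  rbind(o, o + 0.96 * u, o + 0.96 * (cos(1.82) * u + sin(1.82) * v))
}

#' Synthetic water-wire trajectory with known ground truth
#'
#' Builds a membrane-free box with a protein source atom (a gating
#' glutamate carboxylate oxygen at residue 148, plus an anion-pathway
#' marker atom), three lining shells (classes 1-3), decoy waters, a bulk
#' intracellular layer below the inner leaflet plane, and -- in each frame
#' independently with probability \code{wire_probability} -- an intact
#' hydrogen-bonded chain of \code{chain_length} waters at ~2.8 Angstrom
#' spacing running from the source through the requested class shell into
#' bulk.  In unwired frames one mid-chain water is displaced far beyond
#' the H-bond cutoff.  Decoys are placed at least the cutoff + 0.4 A from
#' the chain, the source and each other.
#'
#' @param n_frames frames to generate.
#' @param chain_length waters in the planted chain (>= 2).
#' @param wire_probability per-frame probability of an intact wire.
#' @param n_decoys decoy waters.
#' @param class_route 1, 2 or 3: which class shell the chain runs through.
#' @param seed RNG seed.
#' @param jitter_sd positional jitter per frame, Angstrom.
#' @param frame_interval_ns frame spacing.
#' @return list(trajectory, truth = data.frame(frame, wired), chain_ids,
#'   endpoints, class_defs, membrane, source_region, sink_region).
#' @export
make_wire_fixture <- function(n_frames, chain_length = 5,
                              wire_probability = 0.3, n_decoys = 50,
                              class_route = 2, seed = 1,
                              jitter_sd = 0.04, frame_interval_ns = 0.2) {
  stopifnot(chain_length >= 2, wire_probability >= 0, wire_probability <= 1,
            class_route %in% 1:3)
  set.seed(seed)
  box_half <- 20
  z_inner <- -15; z_outer <- 15
  path_len <- 2.8 * chain_length    # O-O spacing 2.8 A along the route
  route_x <- c(`1` = 6, `2` = 0, `3` = -6)[[as.character(class_route)]]
  src_x <- if (class_route == 1) 6 else 0
  lateral <- abs(route_x - src_x)
  if (path_len^2 <= lateral^2 + 1)
    stop("geometric impossibility: chain too short to span its route")
  # source sits so the last chain water lands 1 A below the inner leaflet
  drop <- sqrt(path_len^2 - lateral^2)
  z_src <- z_inner - 1.0 + drop
  if (z_src > z_outer)
    stop("geometric impossibility: chain longer than the box")
  src_gate <- c(0, 0, if (class_route == 1) z_inner - 1.0 + path_len else
    z_src)
  src_path <- c(6, 0, if (class_route == 1) z_src else
    z_inner - 1.0 + path_len)
  src <- if (class_route == 1) src_path else src_gate
  tgt <- c(route_x, 0, z_inner - 1.0)
  dirv <- (tgt - src) / sqrt(sum((tgt - src)^2))
  chain_o <- t(vapply(seq_len(chain_length),
                      function(k) src + 2.8 * k * dirv, numeric(3)))
  # shells: three pseudo side-chain atoms per class, planted 3 A off the
  # class's route so a routed wire contacts them within the 4 A radius
  shell_frac <- c(0.3, 0.55, 0.8)
  route_point <- function(x_route, frac) {
    s <- c(if (x_route == 6) 6 else 0, 0, NA)
    s[3] <- z_inner - 1.0 + sqrt(path_len^2 - (x_route - s[1])^2)
    tg <- c(x_route, 0, z_inner - 1.0)
    s + frac * (tg - s)
  }
  shells <- lapply(c(6, 0, -6), function(xr)
    t(vapply(shell_frac, function(fr) route_point(xr, fr) + c(0, 3, 0),
             numeric(3))))
  # bulk waters: deep below the leaflet, laterally far from every route
  bulk_o <- cbind(c(14, -14, 14, -14), c(14, -14, -14, 14),
                  z_inner - c(4, 5, 6, 7))
  # decoys by rejection sampling, kept clear of chain/source/each other and
  # of the spot broken-chain waters are parked at
  cutoff_clear <- 3.9
  far_spot <- c(box_half - 2, box_half - 2, z_outer - 2)
  placed <- rbind(chain_o, matrix(src_gate, 1), matrix(src_path, 1), bulk_o,
                  matrix(far_spot, 1))
  decoy_o <- matrix(NA_real_, n_decoys, 3)
  k <- 0
  while (k < n_decoys) {
    cand <- c(stats::runif(2, -box_half, box_half),
              stats::runif(1, z_inner + 3, z_outer))
    d2 <- rowSums(sweep(placed, 2, cand)^2)
    if (min(d2) > cutoff_clear^2) {
      k <- k + 1
      decoy_o[k, ] <- cand
      placed <- rbind(placed, cand)
    }
  }
  # ---- topology ------------------------------------------------------
  atoms <- list()
  add <- function(name, el, resname, resno, chain, role, n = 1)
    data.frame(atom_name = name, element = el, residue_name = resname,
               residue_number = resno, chain_id = chain, role = role)
  rows <- list(
    add("OE1", "O", "GLU", 148, "A", "protein"),
    add("CA", "C", "GLY", 500, "A", "protein"))   # anion-pathway marker
  shell_res <- list(`1` = c(107, 445, 150), `2` = c(202, 203, 113),
                    `3` = c(401, 402, 403))
  shell_resname <- list(`1` = c("SER", "TYR", "GLY"),
                        `2` = c("GLU", "GLU", "GLU"),
                        `3` = c("ALA", "ALA", "ALA"))
  for (cl in 1:3)
    for (m in 1:3)
      rows[[length(rows) + 1]] <- add("CB", "C",
                                      shell_resname[[cl]][m],
                                      shell_res[[cl]][m], "A", "protein")
  n_waters_total <- chain_length + nrow(bulk_o) + n_decoys
  wat_res <- seq_len(n_waters_total) + 1000
  for (w in seq_len(n_waters_total)) {
    rows[[length(rows) + 1]] <- add("OH2", "O", "TIP3", wat_res[w], "W",
                                    "water")
    rows[[length(rows) + 1]] <- add("H1", "H", "TIP3", wat_res[w], "W",
                                    "water")
    rows[[length(rows) + 1]] <- add("H2", "H", "TIP3", wat_res[w], "W",
                                    "water")
  }
  at <- do.call(rbind, rows)
  at$atom_id <- seq_len(nrow(at))
  top <- topology(at)
  n_fixed <- 2 + 9                      # source atoms + shell atoms
  water_o_rows <- n_fixed + 3 * (seq_len(n_waters_total) - 1) + 1
  chain_rows <- water_o_rows[seq_len(chain_length)]
  bulk_rows <- water_o_rows[chain_length + seq_len(nrow(bulk_o))]
  decoy_rows <- water_o_rows[chain_length + nrow(bulk_o) + seq_len(n_decoys)]
  # ---- static base coordinates --------------------------------------
  base <- matrix(0, nrow(at), 3)
  base[1, ] <- src_gate
  base[2, ] <- src_path
  for (cl in 1:3) for (m in 1:3)
    base[2 + (cl - 1) * 3 + m, ] <- shells[[cl]][m, ]
  place_water <- function(base, orow, o, toward = NULL) {
    w <- .water_coords(o, toward)
    base[orow + 0:2, ] <- w
    base
  }
  # donor orientation: water k donates (H1 toward) its predecessor, the
  # first water donates to the source oxygen -- every consecutive pair of
  # the chain then has a near-linear D-H...A arrangement
  for (k in seq_len(chain_length)) {
    toward <- if (k == 1) src else chain_o[k - 1, ]
    base <- place_water(base, chain_rows[k], chain_o[k, ], toward)
  }
  for (b in seq_len(nrow(bulk_o)))
    base <- place_water(base, bulk_rows[b], bulk_o[b, ])
  for (d in seq_len(n_decoys))
    base <- place_water(base, decoy_rows[d], decoy_o[d, ])
  # ---- frames --------------------------------------------------------
  wired <- stats::runif(n_frames) < wire_probability
  coords <- array(NA_real_, c(n_frames, nrow(at), 3))
  broken_k <- ceiling(chain_length / 2)
  for (f in seq_len(n_frames)) {
    fr <- base + matrix(.jit(length(base), jitter_sd), nrow(base), 3)
    if (!wired[f]) {
      orow <- chain_rows[broken_k]
      shift <- far_spot - fr[orow, ]
      fr[orow + 0:2, ] <- fr[orow + 0:2, ] + rep(shift, each = 3)
    }
    coords[f, , ] <- fr
  }
  traj <- trajectory(top, coords, frame_interval_ns)
  membrane <- membrane_frame(z_inner, z_outer)
  source_region <- if (class_route == 1)
    region_spec("anion-pathway", residue_numbers = 500, atom_names = "CA")
  else region_spec("E-gate", residue_numbers = 148, atom_names = "OE1")
  sink_region <- region_spec("bulk-intracellular", role = "water",
                             element = "O", z_below = z_inner)
  class_defs <- list(
    wire_class_def(1, required_source =
                     region_spec("anion-pathway", residue_numbers = 500,
                                 atom_names = "CA"),
                   lining_shell = region_spec("class1-shell",
                                              residue_numbers = shell_res[["1"]],
                                              atom_names = "CB")),
    wire_class_def(2, required_source =
                     region_spec("E-gate", residue_numbers = 148,
                                 atom_names = "OE1"),
                   lining_shell = region_spec("class2-shell",
                                              residue_numbers = shell_res[["2"]],
                                              atom_names = "CB")),
    wire_class_def(3, required_source =
                     region_spec("E-gate", residue_numbers = 148,
                                 atom_names = "OE1"),
                   lining_shell = region_spec("class3-shell",
                                              residue_numbers = shell_res[["3"]],
                                              atom_names = "CB")))
  list(trajectory = traj,
       truth = data.frame(frame = seq_len(n_frames), wired = wired),
       chain_ids = at$atom_id[chain_rows],
       source_id = if (class_route == 1) 2L else 1L,
       endpoints = wire_endpoints(source_region, sink_region),
       class_defs = class_defs, membrane = membrane,
       source_region = source_region, sink_region = sink_region)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic ion random walk with programmed exits
#'
#' Reference geometry: the inner-gate tyrosine hydroxyl oxygen (residue
#' 445, atom OH) at the origin and the serine gate oxygen (residue 107,
#' atom OG) 3 Angstrom away.  Each ion fluctuates around an anchor ~5 A
#' from the reference until its exit time, then drifts at 2 Angstrom/ns
#' along the membrane normal in the programmed direction until far in
#' bulk.  \code{exit_time_ns = NA} means bound forever.
#'
#' @param duration_ns trajectory length.
#' @param exit_time_ns per-ion exit times (NA = never); length = n ions.
#' @param direction per-ion "extracellular" or "intracellular".
#' @param noise_sd positional fluctuation SD, Angstrom (default 0.5).
#' @param seed RNG seed.
#' @param frame_interval_ns frame spacing (default 0.2).
#' @param gate_open_ns optional c(start, end): window in which the
#'   S107-Y445 separation is driven from 3 to 8 Angstrom (gate opening).
#' @return list(trajectory, truth, membrane, pathway_region, ion_ids,
#'   config).
#' @export
make_ion_walk <- function(duration_ns = 1500, exit_time_ns = NA,
                          direction = "extracellular", noise_sd = 0.5,
                          seed = 1, frame_interval_ns = 0.2,
                          gate_open_ns = NULL) {
  set.seed(seed)
  n_ions <- length(exit_time_ns)
  direction <- rep(direction, length.out = n_ions)
  nf <- round(duration_ns / frame_interval_ns)
  t_ns <- seq_len(nf) * frame_interval_ns
  anchors <- list(c(5, 0, 0), c(-5, 0, 0), c(0, 5, 0), c(0, -5, 0))
  rows <- list(
    data.frame(atom_name = "OH", element = "O", residue_name = "TYR",
               residue_number = 445, chain_id = "A", role = "protein"),
    data.frame(atom_name = "OG", element = "O", residue_name = "SER",
               residue_number = 107, chain_id = "A", role = "protein"))
  for (i in seq_len(n_ions))
    rows[[length(rows) + 1]] <-
      data.frame(atom_name = "CLA", element = "Cl", residue_name = "CLA",
                 residue_number = 900 + i, chain_id = "I", role = "ion")
  at <- do.call(rbind, rows)
  at$atom_id <- seq_len(nrow(at))
  top <- topology(at)
  coords <- array(0, c(nf, nrow(at), 3))
  coords[, 1, ] <- 0
  gate_base <- c(3, 0, 0)
  gate_sep <- rep(0, nf)
  if (!is.null(gate_open_ns)) {
    win <- t_ns >= gate_open_ns[1] & t_ns <= gate_open_ns[2]
    gate_sep[win] <- 5            # push OG 5 A further out: 3 -> 8 A
  }
  coords[, 2, 1] <- gate_base[1] + gate_sep +
    .jit(nf, min(noise_sd, 0.1))
  coords[, 2, 2] <- .jit(nf, min(noise_sd, 0.1))
  coords[, 2, 3] <- .jit(nf, min(noise_sd, 0.1))
  drift_rate <- 2                  # Angstrom per ns after exit
  z_cap <- 40
  for (i in seq_len(n_ions)) {
    anc <- anchors[[(i - 1) %% length(anchors) + 1]]
    x <- anc[1] + .jit(nf, noise_sd)
    y <- anc[2] + .jit(nf, noise_sd)
    z <- anc[3] + .jit(nf, noise_sd)
    te <- exit_time_ns[i]
    if (!is.na(te)) {
      sgn <- if (direction[i] == "extracellular") 1 else -1
      out <- t_ns > te
      z[out] <- z[out] + sgn * pmin(drift_rate * (t_ns[out] - te), z_cap)
    }
    coords[, 2 + i, 1] <- x
    coords[, 2 + i, 2] <- y
    coords[, 2 + i, 3] <- z
  }
  traj <- trajectory(top, coords, frame_interval_ns)
  membrane <- membrane_frame(-15, 15)
  pathway_region <- region_spec("inner-gate", residue_numbers = c(107, 445),
                                atom_names = c("OG", "OH"))
  # raw distance sqrt(25 + (drift)^2) crosses 12 A ~5.45 ns after exit
  expected_crossing <- exit_time_ns + sqrt(12^2 - 25) / drift_rate
  list(trajectory = traj,
       truth = data.frame(ion_id = at$atom_id[2 + seq_len(n_ions)],
                          exit_time_ns = exit_time_ns,
                          direction = direction,
                          expected_crossing_ns = expected_crossing),
       membrane = membrane, pathway_region = pathway_region,
       ion_ids = at$atom_id[2 + seq_len(n_ions)],
       config = ion_event_config())
}

#' Synthetic density map with Gaussian blobs on a noise floor
#'
#' @param grid_shape voxel counts per axis (length 3).
#' @param voxel_size Angstrom per voxel.
#' @param blob_centers list of Cartesian centers (or NULL for pure noise).
#' @param blob_sigmas_A blob width per blob, Angstrom.
#' @param blob_peaks peak amplitudes, map units.
#' @param noise_sd baseline noise SD, map units.
#' @param noise_mean baseline mean, map units.
#' @param seed RNG seed.
#' @return list(map, truth): truth holds the analytic approximate peak
#'   z-scores (peak / noise_sd for small blobs on a large grid).
#' @export
make_density_fixture <- function(grid_shape = c(48, 48, 48), voxel_size = 1,
                                 blob_centers = list(c(24, 24, 24)),
                                 blob_sigmas_A = 2, blob_peaks = 8,
                                 noise_sd = 1, noise_mean = 0, seed = 1) {
  set.seed(seed)
  vals <- array(stats::rnorm(prod(grid_shape), noise_mean, noise_sd),
                dim = grid_shape)
  if (length(blob_centers) > 0 && !is.null(blob_centers[[1]])) {
    blob_sigmas_A <- rep(blob_sigmas_A, length.out = length(blob_centers))
    blob_peaks <- rep(blob_peaks, length.out = length(blob_centers))
    ax <- lapply(grid_shape, function(n) (seq_len(n) - 1) * voxel_size)
    for (b in seq_along(blob_centers)) {
      cen <- blob_centers[[b]]
      dx2 <- (ax[[1]] - cen[1])^2
      dy2 <- (ax[[2]] - cen[2])^2
      dz2 <- (ax[[3]] - cen[3])^2
      w <- exp(-outer(outer(dx2, dy2, "+"), dz2, "+") /
                 (2 * blob_sigmas_A[b]^2))
      # blobs replace (not ride on) the noise where they dominate, so the
      # constructed peak value is exactly noise_mean + peak at the center
      vals <- vals * (1 - w) + noise_mean * w + blob_peaks[b] * w
    }
  }
  map <- density_map(vals, voxel_size, origin = c(0, 0, 0))
  truth <- if (length(blob_centers) > 0 && !is.null(blob_centers[[1]]))
    data.frame(center = I(blob_centers), peak = blob_peaks,
               approx_z = blob_peaks / noise_sd)
  else NULL
  list(map = map, truth = truth, noise_sd = noise_sd,
       noise_mean = noise_mean)
}

#' Synthetic deuterium-uptake curves with known protection factors
#'
#' Uptake follows \eqn{D(t) = f \sum_g N_g (1 - e^{-k_{int}(pH) t / P_g})}
#' (one or two protection-factor groups splitting the amides evenly), plus
#' Gaussian noise, clipped to the physical range.  Timepoints default to
#' the experimental grid 20 ... 63,000 s.
#'
#' @param peptides character vector of peptide ids.
#' @param protection_factors list (per peptide) of P, scalar or length 2.
#' @param pH_list labeling pH values.
#' @param timepoints exposure grid, s.
#' @param max_exchangeable amides per peptide (recycled).
#' @param fd_efficiency fully-deuterated plateau efficiency (back-exchange
#'   survival), in (0, 1].
#' @param noise_sd Gaussian noise on deuteration, Da.
#' @param seed RNG seed.
#' @param model intrinsic-rate model (default constants).
#' @return list(curves, fd_controls, truth, model); curves keyed
#'   "peptide pH".
#' @export
make_hdx_curves <- function(peptides, protection_factors, pH_list,
                            timepoints = c(20, 63, 200, 633, 2000, 6325,
                                           20000, 63000),
                            max_exchangeable = 10, fd_efficiency = 0.85,
                            noise_sd = 0.05, seed = 1,
                            model = intrinsic_rate_model()) {
  stopifnot(length(protection_factors) == length(peptides),
            all(unlist(protection_factors) > 0))
  set.seed(seed)
  max_exchangeable <- rep(max_exchangeable, length.out = length(peptides))
  curves <- list(); fd <- list(); truth <- list()
  for (p in seq_along(peptides)) {
    P <- protection_factors[[p]]
    N <- max_exchangeable[p]
    n_groups <- length(P)
    Ng <- rep(N / n_groups, n_groups)
    for (ph in pH_list) {
      k <- intrinsic_rate(model, ph)
      clean <- fd_efficiency *
        rowSums(vapply(seq_len(n_groups), function(g)
          Ng[g] * (1 - exp(-k * timepoints / P[g])), numeric(length(timepoints))))
      d <- pmin(pmax(clean + .jit(length(timepoints), noise_sd), 0), N)
      d <- cummax(d)              # generator curves are monotone by design
      curves[[paste(peptides[p], ph)]] <-
        uptake_curve(peptides[p], ph, timepoints, d, N)
      truth[[paste(peptides[p], ph)]] <-
        list(P = P, k_int = k, clean = clean)
    }
    fd[[peptides[p]]] <- fd_control(peptides[p], fd_efficiency * N)
  }
  list(curves = curves, fd_controls = fd, truth = truth, model = model)
}

#' Synthetic flux-assay trace with programmed transport rates
#'
#' Flat pre-valinomycin baselines; after valinomycin addition the
#' extravesicular chloride rises and the extravesicular pH rises (proton
#' uptake into vesicles) at slopes implied by the per-transporter rates,
#' transporter count, volume and buffering capacity, plus electrode noise.
#'
#' @param cl_rate,h_rate programmed rates, ions/s per transporter.
#' @param params \code{clc_assay_params}; default 6.02e11 transporters,
#'   0.6 mL, 10 mM/pH buffering.
#' @param valinomycin_time_s default 30.
#' @param duration_s default 120.
#' @param sample_hz electrode sampling rate, default 5.
#' @param noise_cl_mM,noise_pH electrode noise SDs.
#' @param cl_baseline_mM starting extravesicular chloride (default 0.05,
#'   i.e. 50 uM).
#' @param pH_baseline starting pH (default 4.5).
#' @param seed RNG seed.
#' @return list(trace, truth, params).
#' @export
make_flux_trace <- function(cl_rate, h_rate,
                            params = assay_params(6.02e11),
                            valinomycin_time_s = 30, duration_s = 120,
                            sample_hz = 5, noise_cl_mM = 2e-4,
                            noise_pH = 1e-4, cl_baseline_mM = 0.05,
                            pH_baseline = 4.5, seed = 1) {
  stopifnot(cl_rate >= 0, h_rate >= 0)
  set.seed(seed)
  t <- seq(0, duration_s, by = 1 / sample_hz)
  post <- pmax(t - valinomycin_time_s, 0)
  cl_slope <- cl_rate * params$n_transporters / .avogadro /
    params$volume_L * 1e3                       # mM/s
  ph_slope <- h_rate * params$n_transporters / .avogadro /
    (params$buffering_capacity * params$volume_L)  # pH/s
  cl <- cl_baseline_mM + cl_slope * post + .jit(length(t), noise_cl_mM)
  ph <- pH_baseline + ph_slope * post + .jit(length(t), noise_pH)
  trace <- flux_trace(t, cl, ph, valinomycin_time_s)
  list(trace = trace,
       truth = list(cl_rate = cl_rate, h_rate = h_rate,
                    stoichiometry = if (h_rate > 0) cl_rate / h_rate else NA,
                    cl_slope_mM_s = cl_slope, ph_slope_s = ph_slope),
       params = params)
}

#' Write a generated fixture to disk in standard formats
#'
#' Trajectory fixtures are written as a PDB topology plus either a DCD or
#' a multi-model PDB; ground truth goes to a JSON sidecar so the test
#' suite can consume it machine-readably.
#'
#' @param fixture result of [make_wire_fixture()] or [make_ion_walk()].
#' @param dir output directory (created).
#' @param traj_format "dcd" or "pdb".
#' @return named list of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir, traj_format = c("dcd", "pdb")) {
  traj_format <- match.arg(traj_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  traj <- fixture$trajectory
  top_path <- file.path(dir, "topology.pdb")
  write_pdb(traj$topology, frame_coords(traj, 1), top_path)
  if (traj_format == "dcd") {
    traj_path <- file.path(dir, "frames.dcd")
    write_dcd(traj, traj_path)
  } else {
    traj_path <- file.path(dir, "frames.pdb")
    write_pdb(traj$topology, traj$coords, traj_path)
  }
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(fixture$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(list(topology = top_path, trajectory = traj_path,
                 truth = truth_path))
}
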