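ion_top <- function(ion_xyz, ref_xyz = c(0, 0, 0)) {
  at <- data.frame(
    atom_id = 1:2, atom_name = c("OH", "CLA"), element = c("O", "Cl"),
    residue_name = c("TYR", "CLA"), residue_number = c(445, 901),
    chain_id = c("A", "I"), role = c("protein", "ion"))
  nf <- nrow(ion_xyz)
  coords <- array(0, c(nf, 2, 3))
  coords[, 1, ] <- matrix(ref_xyz, nf, 3, byrow = TRUE)
  coords[, 2, ] <- ion_xyz
  trajectory(topology(at), coords, 0.2)
}

test_that("minimum-distance series has minimum semantics and an exact constant case", {
  nf <- 20
  traj <- ion_top(matrix(c(rep(5, nf), rep(0, 2 * nf)), nf))
  ser <- min_distance_series(traj)
  expect_equal(ser$raw, rep(5, nf))
  # two ions at 4 and 9 A: the series is the minimum
  at <- data.frame(
    atom_id = 1:3, atom_name = c("OH", "CLA", "CLA"),
    element = c("O", "Cl", "Cl"), residue_name = c("TYR", "CLA", "CLA"),
    residue_number = c(445, 901, 902), chain_id = c("A", "I", "I"),
    role = c("protein", "ion", "ion"))
  coords <- array(0, c(3, 3, 3))
  coords[, 2, 1] <- 4; coords[, 3, 1] <- 9
  tr2 <- trajectory(topology(at), coords, 0.2)
  expect_equal(min_distance_series(tr2)$raw, rep(4, 3))
  # empty ion selection is an error distinct from "far away"
  cfg <- ion_event_config(ion_region = region_spec("none", role = "ion",
                                                   element = "K"))
  expect_error(min_distance_series(tr2, cfg), "empty ion selection")
})

test_that("per-frame minima match an all-pairs brute-force oracle", {
  set.seed(7)
  nf <- 40; n_ions <- 5; n_ref <- 3
  at <- rbind(
    data.frame(atom_id = seq_len(n_ref), atom_name = "OH", element = "O",
               residue_name = "TYR", residue_number = 445, chain_id = "A",
               role = "protein"),
    data.frame(atom_id = n_ref + seq_len(n_ions), atom_name = "CLA",
               element = "Cl", residue_name = "CLA",
               residue_number = 900 + seq_len(n_ions), chain_id = "I",
               role = "ion"))
  coords <- array(rnorm((n_ref + n_ions) * 3 * nf, 0, 8),
                  c(nf, n_ref + n_ions, 3))
  traj <- trajectory(topology(at), coords, 0.2)
  ser <- min_distance_series(traj)
  oracle <- vapply(seq_len(nf), function(f) {
    m <- Inf
    for (r in seq_len(n_ref)) for (i in seq_len(n_ions))
      m <- min(m, sqrt(sum((coords[f, r, ] - coords[f, n_ref + i, ])^2)))
    m
  }, numeric(1))
  expect_equal(ser$raw, oracle)
})

test_that("smoothing: constants unchanged, ramps unchanged in the interior, noise SD shrinks as 1/sqrt(window)", {
  dt <- 0.2
  const <- distance_series(seq_len(300) * dt, rep(5, 300))
  expect_equal(smooth_series(const, 20)$smoothed, rep(5, 300))
  ramp <- distance_series(seq_len(500) * dt, seq(1, 50, length.out = 500))
  sm <- smooth_series(ramp, 20)
  expect_equal(attr(sm, "window_frames"), 101)
  interior <- 51:450
  expect_equal(sm$smoothed[interior], ramp$raw[interior], tolerance = 1e-10)
  set.seed(33)
  noisy <- distance_series(seq_len(5000) * dt, rnorm(5000, 5, 1))
  smn <- smooth_series(noisy, 20)
  sd_obs <- sd(smn$smoothed[101:4900])
  expect_lt(abs(sd_obs - 1 / sqrt(101)) / (1 / sqrt(101)), 0.2)
  expect_error(smooth_series(const, 0.01), "frame interval")
})

test_that("unbinding detection: threshold crossings, spike suppression, padding invariance", {
  dt <- 0.2
  low <- smooth_series(distance_series(seq_len(600) * dt, rep(5, 600)), 20)
  expect_identical(nrow(detect_unbinding(low, 12)), 0L)
  expect_false(attr(detect_unbinding(low, 12), "shows_leaving"))
  # a single-frame raw spike above 12 A is absorbed by the 101-frame window
  spike <- rep(5, 600); spike[300] <- 30
  sp <- smooth_series(distance_series(seq_len(600) * dt, spike), 20)
  expect_identical(nrow(detect_unbinding(sp, 12)), 0L)
  # a genuine exit crosses once and stays out
  exit_raw <- c(rep(5, 300), pmin(5 + 2 * dt * seq_len(300), 35))
  ex <- smooth_series(distance_series(seq_len(600) * dt, exit_raw), 20)
  ev <- detect_unbinding(ex, 12)
  expect_identical(nrow(ev), 1L)
  expect_true(attr(ev, "shows_leaving"))
  # prepending bound-only frames shifts but does not add/remove events
  pad_raw <- c(rep(5, 200), exit_raw)
  pd <- smooth_series(distance_series(seq_len(800) * dt, pad_raw), 20)
  ev2 <- detect_unbinding(pd, 12)
  expect_identical(nrow(ev2), 1L)
  expect_equal(ev2$crossing_time_ns, ev$crossing_time_ns + 200 * dt,
               tolerance = 1e-9)
})

test_that("programmed exits are recovered in time and direction", {
  for (dir in c("extracellular", "intracellular")) {
    fx <- make_ion_walk(duration_ns = 400, exit_time_ns = 250,
                        direction = dir, seed = 17)
    res <- analyze_ion_run(fx$trajectory, fx$config, fx$membrane,
                           fx$pathway_region)
    expect_identical(nrow(res$events), 1L)
    expect_lt(abs(res$events$crossing_time_ns - 250), 10.1)
    expect_identical(res$events$direction, dir)
    expect_true(res$shows_leaving)
  }
  # never-exiting walk: no events, not leaving
  fx0 <- make_ion_walk(duration_ns = 400, exit_time_ns = NA, seed = 18)
  res0 <- analyze_ion_run(fx0$trajectory, fx0$config, fx0$membrane,
                          fx0$pathway_region)
  expect_identical(nrow(res0$events), 0L)
  expect_false(res0$shows_leaving)
  expect_equal(res0$unbound_fraction, 0)
})

test_that("an ion that oscillates without reaching bulk is indeterminate", {
  nf <- 400
  # distance wobbles above/below threshold but never beyond 15 A of origin
  r <- 12.5 + 0.6 * sin(seq_len(nf) / 10)
  ion <- cbind(r, 0, 0)
  traj <- ion_top(ion)
  ser <- smooth_series(min_distance_series(traj), 2)
  ev <- detect_unbinding(ser, 12)
  expect_gt(nrow(ev), 0)
  mem <- membrane_frame(-15, 15)
  path <- region_spec("ref", residue_numbers = 445, atom_names = "OH")
  d <- assign_direction(traj, ev[1, ], mem, path, ion_id = 2)
  expect_identical(d, "indeterminate")
  expect_error(assign_direction(traj, ev[1, ], "not-a-membrane", path, 2),
               "membrane")
})

test_that("unbound occupancy fraction matches programmed bound/unbound split", {
  dt <- 0.2
  bound <- smooth_series(distance_series(seq_len(100) * dt, rep(5, 100)), 2)
  expect_equal(occupancy_fraction(bound, 12), 0)
  unbound <- smooth_series(distance_series(seq_len(100) * dt,
                                           rep(20, 100)), 2)
  expect_equal(occupancy_fraction(unbound, 12), 1)
  # bound 600 ns then unbound 900 ns of a 1500 ns run -> 0.60 unbound
  fx <- make_ion_walk(duration_ns = 1500, exit_time_ns = 600, seed = 5)
  res <- analyze_ion_run(fx$trajectory, fx$config, fx$membrane,
                         fx$pathway_region)
  expect_lt(abs(res$unbound_fraction - 0.6), 0.02)
  # bound + unbound fractions are exact complements
  ser <- res$series
  expect_equal(occupancy_fraction(ser, 12) + mean(ser$smoothed <= 12), 1)
})

test_that("two-ion runs show leaving only after both ions have left", {
  fx <- make_ion_walk(duration_ns = 600, exit_time_ns = c(200, 450),
                      direction = "extracellular", seed = 8)
  res <- analyze_ion_run(fx$trajectory, fx$config, fx$membrane,
                         fx$pathway_region)
  expect_identical(nrow(res$events), 2L)
  expect_true(res$shows_leaving)
  fx2 <- make_ion_walk(duration_ns = 600, exit_time_ns = c(200, NA),
                       direction = "extracellular", seed = 8)
  res2 <- analyze_ion_run(fx2$trajectory, fx2$config, fx2$membrane,
                          fx2$pathway_region)
  expect_false(res2$shows_leaving)
})

test_that("gate series recovers static separations and programmed openings", {
  fx <- make_ion_walk(duration_ns = 100, exit_time_ns = NA, noise_sd = 0,
                      seed = 3)
  gs <- gate_series(fx$trajectory)
  expect_equal(gs$raw, rep(3, length(gs$raw)))
  expect_equal(attr(gs, "open_fraction"), 0)
  fx2 <- make_ion_walk(duration_ns = 100, exit_time_ns = NA, noise_sd = 0,
                       seed = 3, gate_open_ns = c(40, 60))
  gs2 <- gate_series(fx2$trajectory)
  open <- gs2$times_ns >= 40 & gs2$times_ns <= 60
  expect_equal(gs2$raw[open], rep(8, sum(open)))
  expect_equal(attr(gs2, "open_fraction"), mean(open))
  # pure per-frame map: frame reversal reverses the series
  rev_traj <- fx2$trajectory
  rev_traj$coords <- rev_traj$coords[rev(seq_len(n_frames(rev_traj))), , ,
                                     drop = FALSE]
  expect_equal(gate_series(rev_traj)$raw, rev(gs2$raw))
  # missing gate residues are reported by name
  small <- ion_top(matrix(5, 4, 3))
  expect_error(gate_series(small), "S107")
})
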