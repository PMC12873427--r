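test_that("map statistics: constant maps are degenerate, noise maps calibrate, affine identities hold", {
  const <- density_map(array(3, c(5, 5, 5)), 1)
  st <- map_statistics(const)
  expect_equal(st$sd, 0)
  expect_error(zscore_at(const, c(2, 2, 2), st), "degenerate")
  fx <- make_density_fixture(grid_shape = c(32, 32, 32),
                             blob_centers = list(NULL), seed = 6)
  st2 <- map_statistics(fx$map)
  n <- prod(dim(fx$map$values))
  expect_lt(abs(st2$mean - 0), 3 / sqrt(n))
  expect_lt(abs(st2$sd - 1), 3 / sqrt(n))
  # affine rescale a*x + b: mean and sd transform accordingly
  resc <- fx$map
  resc$values <- 2.5 * resc$values + 7
  st3 <- map_statistics(resc)
  expect_equal(st3$mean, 2.5 * st2$mean + 7, tolerance = 1e-12)
  expect_equal(st3$sd, 2.5 * st2$sd, tolerance = 1e-12)
})

test_that("z-score: voxel-mean zero, planted blob ~8 sigma, affine invariance, bounds", {
  fx <- make_density_fixture(grid_shape = c(48, 48, 48),
                             blob_centers = list(c(24, 24, 24)),
                             blob_peaks = 8, noise_sd = 1, seed = 12)
  st <- map_statistics(fx$map)
  z <- zscore_at(fx$map, c(24, 24, 24), st)
  expect_lt(abs(z - 8), 0.2)
  # z-score invariant under affine rescaling of all map values
  resc <- fx$map
  resc$values <- -3 * resc$values + 11
  expect_equal(abs(zscore_at(resc, c(24, 24, 24))), abs(z),
               tolerance = 1e-9)
  # interpolation consistency: at a grid node, trilinear = direct lookup
  v <- fx$map$values[11, 17, 23]
  expect_equal(zscore_at(fx$map, c(10, 16, 22), st),
               (v - st$mean) / st$sd, tolerance = 1e-12)
  expect_equal(zscore_at(fx$map, c(10, 16, 22), st, "nearest"),
               (v - st$mean) / st$sd, tolerance = 1e-12)
  expect_error(zscore_at(fx$map, c(100, 0, 0), st), "bounds")
  # a coordinate at a voxel whose value equals the mean scores zero
  m2 <- fx$map
  m2$values[2, 2, 2] <- st$mean
  expect_equal(zscore_at(m2, c(1, 1, 1), st), 0, tolerance = 1e-12)
})

test_that("stronger sites keep their z ordering through the pipeline", {
  strong <- make_density_fixture(blob_peaks = 11.1, seed = 3)
  weak <- make_density_fixture(blob_peaks = 7.9, seed = 3)
  zs <- zscore_at(strong$map, c(24, 24, 24))
  zw <- zscore_at(weak$map, c(24, 24, 24))
  expect_gt(zs, zw)
  expect_lt(abs(zs - 11.1), 0.4)
  expect_lt(abs(zw - 7.9), 0.4)
})

test_that("MRC round trip preserves grid, voxel size, origin and values", {
  fx <- make_density_fixture(grid_shape = c(20, 24, 28), voxel_size = 1.1,
                             blob_centers = list(c(11, 13, 15)), seed = 9)
  fx$map$origin <- c(-5, 2, 7)
  path <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(fx$map, path)
  m2 <- read_mrc(path)
  expect_identical(dim(m2$values), dim(fx$map$values))
  expect_equal(m2$voxel_size, fx$map$voxel_size, tolerance = 1e-6)
  expect_equal(m2$origin, fx$map$origin, tolerance = 1e-6)
  expect_lt(max(abs(m2$values - fx$map$values)), 1e-5)
})

test_that("residue pairing: identity, deletions and shuffled chain ids", {
  ma <- make_helix_model(50, seed = 2)
  p <- pair_residues(ma, ma)
  expect_identical(nrow(p), 50L)
  expect_identical(p$resno_a, p$resno_b)
  # delete 5 residues from the middle of B: pairing skips exactly those
  mb <- ma
  drop <- 20:24
  keep <- !(mb$topology$atoms$residue_number %in% drop)
  mb$topology <- topology(mb$topology$atoms[keep, ])
  mb$coords <- mb$coords[keep, , drop = FALSE]
  p2 <- pair_residues(ma, mb)
  expect_identical(nrow(p2), 45L)
  expect_false(any(p2$resno_a %in% drop))
  # relabeled chains with identical sequences: recovered via best match
  mc <- ma
  mc$topology$atoms$chain_id <- "Q"
  p3 <- pair_residues(ma, mc)
  expect_identical(nrow(p3), 50L)
  # no common residues is an error
  md <- ma
  md$topology$atoms$role <- "other"
  expect_error(pair_residues(ma, md), "C-alpha")
})

test_that("superposition: exact rigid recovery, symmetry, proper rotation", {
  ma <- make_helix_model(60, seed = 4)
  mb <- rigid_transform_model(ma, angles = c(0.4, -1.1, 2.2),
                              translation = c(12, -7, 3))
  al <- superpose_rmsd(ma, mb)
  expect_lt(al$rmsd, 1e-6)
  expect_equal(det(al$rotation), 1, tolerance = 1e-9)
  expect_equal(t(al$rotation) %*% al$rotation, diag(3), tolerance = 1e-9)
  mc <- perturb_model(ma, 0.8, seed = 5)
  expect_equal(superpose_rmsd(ma, mc)$rmsd, superpose_rmsd(mc, ma)$rmsd,
               tolerance = 1e-9)
  # RMSD invariant to a rigid transform of either input
  expect_equal(superpose_rmsd(rigid_transform_model(ma), mc)$rmsd,
               superpose_rmsd(ma, mc)$rmsd, tolerance = 1e-9)
  expect_error(superpose_rmsd(ma, mc, pairing = pair_residues(ma, mc)[1:2, ]),
               "3")
})

test_that("3-point superposition matches a closed-form planar oracle", {
  # planar sets: optimal rotation angle has the classic 2-D closed form
  P <- cbind(c(0, 4, 1), c(0, 0, 3), 0)
  Q0 <- cbind(c(0.2, 4.1, 0.8), c(-0.1, 0.3, 3.2), 0)
  theta <- 0.7
  R2 <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2)
  Q <- Q0
  Q[, 1:2] <- Q0[, 1:2] %*% t(R2)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  th_opt <- atan2(sum(Qc[, 1] * Pc[, 2] - Qc[, 2] * Pc[, 1]),
                  sum(Qc[, 1] * Pc[, 1] + Qc[, 2] * Pc[, 2]))
  Ropt <- matrix(c(cos(th_opt), -sin(th_opt), sin(th_opt), cos(th_opt)), 2,
                 byrow = TRUE)
  Qrot <- Qc
  Qrot[, 1:2] <- Qc[, 1:2] %*% t(Ropt)
  rmsd_oracle <- sqrt(mean(rowSums((Pc - Qrot)^2)))
  mk <- function(coords) {
    at <- data.frame(atom_id = 1:3, atom_name = "CA", element = "C",
                     residue_name = "ALA", residue_number = 1:3,
                     chain_id = "A", role = "protein")
    structure(list(topology = topology(at), coords = coords,
                   format = "pdb"), class = "clc_model")
  }
  al <- superpose_rmsd(mk(P), mk(Q))
  expect_equal(al$rmsd, rmsd_oracle, tolerance = 1e-9)
})

test_that("RMSD agrees with the bio3d reference implementation", {
  ma <- make_helix_model(40, seed = 7)
  mb <- perturb_model(ma, 1.2, seed = 8)
  al <- superpose_rmsd(ma, mb)
  ref <- bio3d::rmsd(as.vector(t(ma$coords)), as.vector(t(mb$coords)),
                     fit = TRUE)
  expect_equal(al$rmsd, ref, tolerance = 1e-3)
})

test_that("matchmaker-like pruning drops outlier pairs and reports both values", {
  ma <- make_helix_model(60, seed = 10)
  mb <- perturb_model(ma, 0.3, seed = 11)
  mb$coords[5, ] <- mb$coords[5, ] + c(15, 0, 0)   # one gross outlier
  al <- superpose_rmsd(ma, mb, prune_cutoff = 2.0)
  expect_gt(al$rmsd, al$rmsd_pruned)
  expect_gte(al$n_pruned, 1)
  expect_lt(al$rmsd_pruned, 0.5)
})
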