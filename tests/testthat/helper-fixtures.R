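# hand-built micro-fixtures used across test files

# topology of n waters (O + optional 2 H each) at given oxygen positions;
# h_offsets: list per water of 2x3 H offsets from the O, or NULL for no H
water_box <- function(o_pos, h_offsets = NULL, extra_atoms = NULL) {
  rows <- list()
  coords <- list()
  for (w in seq_len(nrow(o_pos))) {
    rows[[length(rows) + 1]] <- data.frame(
      atom_name = "OH2", element = "O", residue_name = "TIP3",
      residue_number = 1000 + w, chain_id = "W", role = "water")
    coords[[length(coords) + 1]] <- o_pos[w, , drop = FALSE]
    if (!is.null(h_offsets)) {
      for (h in 1:2) {
        rows[[length(rows) + 1]] <- data.frame(
          atom_name = paste0("H", h), element = "H", residue_name = "TIP3",
          residue_number = 1000 + w, chain_id = "W", role = "water")
        coords[[length(coords) + 1]] <-
          o_pos[w, , drop = FALSE] + h_offsets[[w]][h, , drop = FALSE]
      }
    }
  }
  if (!is.null(extra_atoms)) {
    rows[[length(rows) + 1]] <- extra_atoms$atoms
    coords[[length(coords) + 1]] <- extra_atoms$coords
  }
  at <- do.call(rbind, rows)
  at$atom_id <- seq_len(nrow(at))
  list(topology = topology(at), frame = do.call(rbind, coords))
}

# random water frame: oxygens uniform in a box, two random unit-ish H's each
random_water_frame <- function(n_waters, box = 30, seed = 1) {
  set.seed(seed)
  o <- matrix(runif(n_waters * 3, 0, box), ncol = 3)
  hoff <- lapply(seq_len(n_waters), function(i) {
    u <- matrix(rnorm(6), 2); u / sqrt(rowSums(u^2)) * 0.96
  })
  water_box(o, hoff)
}

# independent edge check: recompute distance + best D-H...A angle directly
oracle_hbond_ok <- function(frame, topology, id_a, id_b, criteria) {
  a <- topology$atoms
  ra <- match(id_a, a$atom_id); rb <- match(id_b, a$atom_id)
  d <- sqrt(sum((frame[ra, ] - frame[rb, ])^2))
  if (d > criteria$d_da_max) return(FALSE)
  if (!criteria$use_hydrogens) return(TRUE)
  res_key <- paste(a$chain_id, a$residue_number)
  hyd <- function(r) {
    cand <- which(a$element == "H" & res_key == res_key[r])
    if (length(cand) == 0) return(integer(0))
    cand[sqrt(rowSums((frame[cand, , drop = FALSE] -
                         matrix(frame[r, ], length(cand), 3,
                                byrow = TRUE))^2)) <= 1.3]
  }
  ang <- function(h, dd, aa) {
    v1 <- frame[dd, ] - frame[h, ]; v2 <- frame[aa, ] - frame[h, ]
    acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) *
      180 / pi
  }
  best <- -Inf
  for (h in hyd(ra)) best <- max(best, ang(h, ra, rb))
  for (h in hyd(rb)) best <- max(best, ang(h, rb, ra))
  is.finite(best) && best >= criteria$angle_min_deg
}
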