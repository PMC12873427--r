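#' Geometric hydrogen-bond criteria
#'
#' Standard water H-bond geometry: heavy-atom donor-acceptor distance at
#' most \code{d_da_max} (default 3.5 Angstrom) and a D-H...A angle of at
#' least \code{angle_min_deg} (default 150 degrees).  With
#' \code{use_hydrogens = FALSE} the angle test is skipped (distance-only
#' mode, a superset of the angular mode at equal cutoff).
#'
#' @param d_da_max donor-acceptor heavy-atom cutoff, Angstrom (0, 6].
#' @param angle_min_deg minimum D-H...A angle, degrees (0, 180].
#' @param use_hydrogens logical; if TRUE hydrogens must be present.
#' @return object of class \code{clc_hbond_criteria}.
#' @export
hbond_criteria <- function(d_da_max = 3.5, angle_min_deg = 150,
                           use_hydrogens = TRUE) {
  stopifnot(d_da_max > 0, d_da_max <= 6,
            angle_min_deg > 0, angle_min_deg <= 180)
  structure(list(d_da_max = d_da_max, angle_min_deg = angle_min_deg,
                 use_hydrogens = use_hydrogens),
            class = "clc_hbond_criteria")
}

# hydrogens covalently attached to each heavy node atom: same residue and
# within 1.3 A in the given frame
.attached_hydrogens <- function(topology, frame, node_rows) {
  a <- topology$atoms
  h_rows <- which(a$element == "H")
  if (length(h_rows) == 0)
    return(rep(list(integer(0)), length(node_rows)))
  res_key <- paste(a$chain_id, a$residue_number)
  h_by_res <- split(h_rows, res_key[h_rows])
  lapply(node_rows, function(r) {
    cand <- h_by_res[[res_key[r]]]
    if (is.null(cand)) return(integer(0))
    d2 <- (frame[cand, 1] - frame[r, 1])^2 +
      (frame[cand, 2] - frame[r, 2])^2 + (frame[cand, 3] - frame[r, 3])^2
    cand[d2 <= 1.3^2]
  })
}

# candidate node pairs within cutoff; returns two-column index matrix into
# node list (i < j).  method "grid" uses a cell list, "brute" a full
# distance matrix; both must agree (property-tested).
.pairs_within <- function(xyz, cutoff, method = c("grid", "brute")) {
  method <- match.arg(method)
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  if (method == "brute") {
    d <- as.matrix(stats::dist(xyz))
    idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    dimnames(idx) <- NULL
    storage.mode(idx) <- "integer"
    return(idx)
  }
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  nx <- max(cell[, 1]) + 1; ny <- max(cell[, 2]) + 1
  nz <- max(cell[, 3]) + 1
  key <- cell[, 1] + nx * (cell[, 2] + ny * cell[, 3])
  groups <- split(seq_len(n), key)
  key_of <- function(cx, cy, cz) cx + nx * (cy + ny * cz)
  out_i <- integer(0); out_j <- integer(0)
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  # keep only "forward" offsets so each cell pair is visited once
  offsets <- offsets[with(offsets, dz > 0 | (dz == 0 & (dy > 0 | (dy == 0 & dx >= 0)))), ]
  for (g in names(groups)) {
    members <- groups[[g]]
    k <- as.numeric(g)
    cz <- k %/% (nx * ny); rem <- k %% (nx * ny)
    cy <- rem %/% nx; cx <- rem %% nx
    for (o in seq_len(nrow(offsets))) {
      dx <- offsets$dx[o]; dy <- offsets$dy[o]; dz <- offsets$dz[o]
      tx <- cx + dx; ty <- cy + dy; tz <- cz + dz
      if (tx < 0 || tx >= nx || ty < 0 || ty >= ny || tz < 0 || tz >= nz)
        next                       # outside the grid: no aliased key lookups
      same <- dx == 0 && dy == 0 && dz == 0
      nb <- groups[[as.character(key_of(tx, ty, tz))]]
      if (is.null(nb)) next
      if (same) {
        if (length(members) < 2) next
        cmb <- utils::combn(members, 2)
        ii <- cmb[1, ]; jj <- cmb[2, ]
      } else {
        ii <- rep(members, each = length(nb))
        jj <- rep(nb, times = length(members))
      }
      d2 <- (xyz[ii, 1] - xyz[jj, 1])^2 + (xyz[ii, 2] - xyz[jj, 2])^2 +
        (xyz[ii, 3] - xyz[jj, 3])^2
      ok <- d2 <= cutoff^2
      out_i <- c(out_i, ii[ok]); out_j <- c(out_j, jj[ok])
    }
  }
  if (length(out_i) == 0) return(matrix(integer(0), ncol = 2))
  idx <- cbind(pmin(out_i, out_j), pmax(out_i, out_j))
  idx <- unique(idx)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  dimnames(idx) <- NULL
  storage.mode(idx) <- "integer"
  idx
}

.angle_deg <- function(h, d, a) {
  # D-H...A angle evaluated at the hydrogen
  v1 <- d - h; v2 <- a - h
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect geometric hydrogen bonds over a node set in one frame
#'
#' Builds the undirected H-bond graph over the requested heavy atoms (water
#' oxygens plus any designated protein endpoint atoms).  An edge requires
#' the heavy-atom distance criterion and, in angular mode, a near-linear
#' D-H...A arrangement with the hydrogen donated by either partner.
#' Protein endpoint atoms without attached hydrogens participate as
#' acceptors.  Edges are stored in sorted (min, max) atom-id order, so the
#' edge list is reproducible bit-exactly for a fixed frame.
#'
#' @param frame n_atoms x 3 coordinate matrix (Angstrom).
#' @param topology \code{clc_topology}.
#' @param node_set atom ids to build the graph over (nonempty).
#' @param criteria \code{clc_hbond_criteria}.
#' @param frame_index stored in the result for bookkeeping.
#' @param method "grid" (cell-list accelerated, default) or "brute"
#'   (all-pairs); results are identical.
#' @return object of class \code{clc_hbond_graph}: list(frame_index, nodes,
#'   edges) where edges is a data.frame(i, j, distance, angle) keyed by
#'   atom id (angle NA in distance-only mode).
#' @export
detect_hbonds <- function(frame, topology, node_set, criteria = hbond_criteria(),
                          frame_index = 1L, method = c("grid", "brute")) {
  method <- match.arg(method)
  if (length(node_set) == 0) stop("node_set must be nonempty")
  a <- topology$atoms
  rows <- match(node_set, a$atom_id)
  if (anyNA(rows)) stop("node_set contains unknown atom ids")
  ord <- order(a$atom_id[rows])
  rows <- rows[ord]
  ids <- a$atom_id[rows]
  xyz <- frame[rows, , drop = FALSE]
  if (criteria$use_hydrogens) {
    hyd <- .attached_hydrogens(topology, frame, rows)
    if (all(lengths(hyd) == 0))
      stop("use_hydrogens = TRUE but no hydrogens attached to any node; ",
           "supply hydrogens or use distance-only criteria")
  }
  cand <- .pairs_within(xyz, criteria$d_da_max, method)
  if (nrow(cand) == 0) {
    edges <- data.frame(i = integer(0), j = integer(0),
                        distance = numeric(0), angle = numeric(0))
    return(structure(list(frame_index = frame_index, nodes = ids,
                          edges = edges, criteria = criteria),
                     class = "clc_hbond_graph"))
  }
  di <- sqrt(rowSums((xyz[cand[, 1], , drop = FALSE] -
                        xyz[cand[, 2], , drop = FALSE])^2))
  if (!criteria$use_hydrogens) {
    keep <- rep(TRUE, nrow(cand))
    ang <- rep(NA_real_, nrow(cand))
  } else {
    keep <- logical(nrow(cand))
    ang <- rep(NA_real_, nrow(cand))
    for (k in seq_len(nrow(cand))) {
      p <- cand[k, 1]; q <- cand[k, 2]
      best <- -Inf
      for (h in hyd[[p]]) {                     # p donates to q
        aa <- .angle_deg(frame[h, ], xyz[p, ], xyz[q, ])
        if (aa > best) best <- aa
      }
      for (h in hyd[[q]]) {                     # q donates to p
        aa <- .angle_deg(frame[h, ], xyz[q, ], xyz[p, ])
        if (aa > best) best <- aa
      }
      if (is.finite(best)) ang[k] <- best
      keep[k] <- is.finite(best) && best >= criteria$angle_min_deg
    }
  }
  edges <- data.frame(i = ids[cand[keep, 1]], j = ids[cand[keep, 2]],
                      distance = di[keep], angle = ang[keep])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(frame_index = frame_index, nodes = ids, edges = edges,
                 criteria = criteria),
            class = "clc_hbond_graph")
}

#' @export
print.clc_hbond_graph <- function(x, ...) {
  cat("<clc_hbond_graph> frame ", x$frame_index, ": ", length(x$nodes),
      " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Export an H-bond graph edge list as TSV
#' @param graph \code{clc_hbond_graph}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_hbond_tsv <- function(graph, path) {
  df <- cbind(frame = graph$frame_index, graph$edges)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
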