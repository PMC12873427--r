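# Calpha extraction: one row per protein residue with a CA atom
.calpha_table <- function(model) {
  a <- model$topology$atoms
  sel <- which(a$role == "protein" & a$atom_name == "CA")
  if (length(sel) == 0) stop("model has no protein C-alpha atoms")
  data.frame(chain = a$chain_id[sel], resno = a$residue_number[sel],
             aa = bio3d::aa321(a$residue_name[sel]),
             row = sel, stringsAsFactors = FALSE)
}

# global alignment of two one-letter sequences; returns index pairs
.align_seqs <- function(sa, sb) {
  if (identical(sa, sb))
    return(cbind(seq_along(sa), seq_along(sb)))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(sa, collapse = "")),
    Biostrings::AAString(paste(sb, collapse = "")),
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = 10, gapExtension = 0.5, type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- 0L; ib <- 0L
  out <- matrix(integer(0), ncol = 2)
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ia <- ia + 1L
    if (pb[k] != "-") ib <- ib + 1L
    if (pa[k] != "-" && pb[k] != "-" && pa[k] == pb[k])
      out <- rbind(out, c(ia, ib))
  }
  out
}

.align_score <- function(sa, sb) {
  nrow(rbind(.align_seqs(sa, sb)))
}

#' Pair residues between two atomic models
#'
#' Chain-aware sequence-alignment pairing of protein C-alpha residues, in
#' the spirit of matchmaker-style structural alignment: chains are matched
#' by best alignment overlap (greedy), sequences within matched chains are
#' globally aligned, and unmatched residues are excluded.  Identical
#' sequences reduce to the identity pairing.
#'
#' @param model_a,model_b \code{clc_model} objects with protein C-alpha
#'   atoms.
#' @return data.frame(chain_a, resno_a, row_a, chain_b, resno_b, row_b),
#'   one row per paired residue (rows index the models' coordinate
#'   matrices).
#' @export
pair_residues <- function(model_a, model_b) {
  ca <- .calpha_table(model_a)
  cb <- .calpha_table(model_b)
  chains_a <- split(ca, ca$chain)
  chains_b <- split(cb, cb$chain)
  # greedy chain correspondence by alignment overlap
  combos <- expand.grid(a = names(chains_a), b = names(chains_b),
                        stringsAsFactors = FALSE)
  combos$score <- mapply(function(x, y)
    .align_score(chains_a[[x]]$aa, chains_b[[y]]$aa), combos$a, combos$b)
  combos <- combos[order(-combos$score), ]
  used_a <- character(0); used_b <- character(0)
  pairs <- list()
  for (k in seq_len(nrow(combos))) {
    x <- combos$a[k]; y <- combos$b[k]
    if (x %in% used_a || y %in% used_b || combos$score[k] == 0) next
    used_a <- c(used_a, x); used_b <- c(used_b, y)
    ta <- chains_a[[x]]; tb <- chains_b[[y]]
    idx <- .align_seqs(ta$aa, tb$aa)
    if (nrow(idx) == 0) next
    pairs[[length(pairs) + 1]] <-
      data.frame(chain_a = ta$chain[idx[, 1]], resno_a = ta$resno[idx[, 1]],
                 row_a = ta$row[idx[, 1]],
                 chain_b = tb$chain[idx[, 2]], resno_b = tb$resno[idx[, 2]],
                 row_b = tb$row[idx[, 2]], stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0) stop("no common residues between models")
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  out
}

# Kabsch: optimal proper rotation of Q onto P (both n x 3, centered)
.kabsch <- function(Pc, Qc) {
  H <- t(Qc) %*% Pc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

.fit_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  R <- .kabsch(Pc, Qc)
  Qrot <- Qc %*% t(R)
  dev <- sqrt(rowSums((Pc - Qrot)^2))
  list(rotation = R, translation = as.numeric(cp - R %*% cq),
       rmsd = sqrt(mean(dev^2)), deviations = dev)
}

#' Least-squares C-alpha superposition and RMSD
#'
#' Kabsch superposition of model B onto model A over the paired C-alpha
#' atoms (proper rotation, determinant +1).  With a prune cutoff, pairs
#' deviating beyond the cutoff are dropped iteratively and the fit repeated
#' until stable (matchmaker-like); the all-pair RMSD is always reported
#' alongside the post-prune value.
#'
#' @param model_a,model_b \code{clc_model} objects.
#' @param pairing result of [pair_residues()]; computed if missing.
#' @param prune_cutoff Angstrom, or NULL (default) for no pruning.
#' @return list(rotation, translation, rmsd, rmsd_pruned, n_pairs,
#'   n_pruned, pairing, deviations); \code{rmsd} is the all-pair value.
#' @export
superpose_rmsd <- function(model_a, model_b, pairing = NULL,
                           prune_cutoff = NULL) {
  if (is.null(pairing)) pairing <- pair_residues(model_a, model_b)
  if (nrow(pairing) < 3) stop("need at least 3 residue pairs")
  P <- model_a$coords[pairing$row_a, , drop = FALSE]
  Q <- model_b$coords[pairing$row_b, , drop = FALSE]
  fit_all <- .fit_rmsd(P, Q)
  rmsd_pruned <- NA_real_
  n_pruned <- 0L
  fit <- fit_all
  if (!is.null(prune_cutoff)) {
    keep <- rep(TRUE, nrow(P))
    repeat {
      fitk <- .fit_rmsd(P[keep, , drop = FALSE], Q[keep, , drop = FALSE])
      bad <- which(keep)[fitk$deviations > prune_cutoff]
      if (length(bad) == 0 || sum(keep) - length(bad) < 3) {
        fit <- fitk
        break
      }
      keep[bad] <- FALSE
    }
    n_pruned <- sum(!keep)
    rmsd_pruned <- fit$rmsd
  }
  list(rotation = fit_all$rotation, translation = fit_all$translation,
       rmsd = fit_all$rmsd, rmsd_pruned = rmsd_pruned,
       n_pairs = nrow(pairing), n_pruned = n_pruned,
       pairing = pairing, deviations = fit_all$deviations)
}
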