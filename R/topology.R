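#' @importFrom stats median quantile sd setNames coef
#' @importFrom utils head tail write.table read.delim
NULL

# Residue-name tables used for role assignment.  User-extensible via the
# load_topology() arguments; defaults cover CHARMM/AMBER/GROMACS conventions.
.default_water_resnames <- c("HOH", "WAT", "TIP3", "SOL", "TIP", "SPC", "TP3")
.default_ion_resnames   <- c("CL", "CLA", "NA", "SOD", "K", "POT", "CAL",
                             "MG", "ZN", "CES", "LIT")
.default_lipid_resnames <- c("POPC", "POPE", "POPG", "POPS", "DPPC", "DMPC",
                             "DOPC", "CHL1", "PA", "PC", "PE", "PG", "OL")
.aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","HSD","HSE",
          "HSP","HID","HIE","HIP","ILE","LEU","LYS","MET","PHE","PRO","SER",
          "THR","TRP","TYR","VAL","MSE","ASH","GLH","LYN","CYX","CYM")

#' Construct a molecular topology
#'
#' A topology is the static atom table underlying all trajectory analyses:
#' one row per atom with identity, residue assignment, chain, and a coarse
#' role (\code{protein}, \code{water}, \code{ion}, \code{lipid},
#' \code{other}).  Atom ids must be unique; they index the coordinate arrays
#' of every [trajectory()] built on the topology.
#'
#' @param atoms data.frame with columns \code{atom_id} (integer, unique),
#'   \code{atom_name}, \code{element}, \code{residue_name},
#'   \code{residue_number}, \code{chain_id}, \code{role}.
#' @return An object of class \code{clc_topology}.
#' @export
topology <- function(atoms) {
  req <- c("atom_id", "atom_name", "element", "residue_name",
           "residue_number", "chain_id", "role")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0)
    stop("topology atom table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(atoms$atom_id))
    stop("atom_ids must be unique")
  ok_roles <- c("protein", "water", "ion", "lipid", "other")
  bad <- setdiff(unique(atoms$role), ok_roles)
  if (length(bad) > 0)
    stop("unknown roles: ", paste(bad, collapse = ", "))
  atoms <- atoms[order(atoms$atom_id), req, drop = FALSE]
  atoms$atom_id <- as.integer(atoms$atom_id)
  atoms$residue_number <- as.integer(atoms$residue_number)
  rownames(atoms) <- NULL
  # every water residue must contain an oxygen
  wat <- atoms[atoms$role == "water", , drop = FALSE]
  if (nrow(wat) > 0) {
    has_o <- tapply(wat$element == "O", paste(wat$chain_id, wat$residue_number),
                    any)
    if (!all(has_o))
      stop("water residue(s) without an oxygen atom")
    has_h <- any(wat$element == "H")
  } else has_h <- FALSE
  structure(list(atoms = atoms, waters_have_hydrogens = has_h),
            class = "clc_topology")
}

#' @export
print.clc_topology <- function(x, ...) {
  tab <- table(x$atoms$role)
  cat("<clc_topology> ", nrow(x$atoms), " atoms (",
      paste(names(tab), as.integer(tab), sep = ":", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Number of atoms in a topology, trajectory or model
#' @param x object
#' @return integer atom count
#' @export
n_atoms <- function(x) {
  if (inherits(x, "clc_topology")) return(nrow(x$atoms))
  if (inherits(x, "clc_trajectory")) return(nrow(x$topology$atoms))
  if (inherits(x, "clc_model")) return(nrow(x$topology$atoms))
  stop("n_atoms: unsupported object")
}

.assign_roles <- function(resnames, water_resnames, ion_resnames,
                          lipid_resnames) {
  role <- rep("other", length(resnames))
  role[resnames %in% .aa3] <- "protein"
  role[resnames %in% water_resnames] <- "water"
  role[resnames %in% ion_resnames] <- "ion"
  role[resnames %in% lipid_resnames] <- "lipid"
  role
}

.guess_element <- function(atom_name, resname, role) {
  # PDB element guess from atom name; ions map whole-name
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  el <- substr(nm, 1, 1)
  el[role == "ion"] <- vapply(nm[role == "ion"], function(s) {
    if (s %in% c("CL", "CLA")) "Cl"
    else if (s %in% c("NA", "SOD")) "Na"
    else if (s %in% c("K", "POT")) "K"
    else if (s %in% c("MG")) "Mg"
    else if (s %in% c("CAL", "CA")) "Ca"
    else substr(s, 1, 1)
  }, character(1))
  el
}

#' Load a topology (and coordinates) from a PDB file
#'
#' Reads a PDB file through \pkg{bio3d} and assigns each atom a role from
#' configurable residue-name tables.  Unrecognized residue names are
#' assigned role \code{other} with a warning, never an error.
#'
#' @param path PDB file.
#' @param water_resnames,ion_resnames,lipid_resnames residue-name tables.
#' @param quiet suppress the atom-count message.
#' @return \code{clc_topology}; first-model coordinates are attached as
#'   attribute \code{"coords"} (n_atoms x 3 matrix, Angstrom).
#' @export
load_topology <- function(path,
                          water_resnames = .default_water_resnames,
                          ion_resnames = .default_ion_resnames,
                          lipid_resnames = .default_lipid_resnames,
                          quiet = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file '", path,
                                           "': ", conditionMessage(e)))
  a <- pdb$atom
  role <- .assign_roles(a$resid, water_resnames, ion_resnames, lipid_resnames)
  unknown <- unique(a$resid[role == "other"])
  if (length(unknown) > 0)
    warning("unrecognized residue name(s) assigned role 'other': ",
            paste(unknown, collapse = ", "))
  elem <- a$elesy
  need_guess <- is.na(elem) | elem == ""
  if (any(need_guess))
    elem[need_guess] <- .guess_element(a$elety[need_guess],
                                       a$resid[need_guess], role[need_guess])
  chain <- a$chain
  chain[is.na(chain)] <- " "
  atoms <- data.frame(atom_id = seq_len(nrow(a)),
                      atom_name = a$elety,
                      element = elem,
                      residue_name = a$resid,
                      residue_number = a$resno,
                      chain_id = chain,
                      role = role,
                      stringsAsFactors = FALSE)
  top <- topology(atoms)
  if (!quiet)
    message("load_topology: ", nrow(atoms), " atoms from ", basename(path))
  coords <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  if (!all(is.finite(coords))) stop("non-finite coordinates in ", path)
  attr(top, "coords") <- coords
  top
}

#' Load an atomic model (single structure) from PDB or mmCIF
#'
#' @param path PDB or mmCIF file (format chosen by extension; \code{.cif}
#'   read with \code{bio3d::read.cif}).
#' @inheritParams load_topology
#' @return object of class \code{clc_model}: list(topology, coords, format).
#' @export
load_model <- function(path,
                       water_resnames = .default_water_resnames,
                       ion_resnames = .default_ion_resnames,
                       lipid_resnames = .default_lipid_resnames,
                       quiet = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "cif") {
    pdb <- bio3d::read.cif(path, verbose = FALSE)
    fmt <- "mmcif"
  } else {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    fmt <- "pdb"
  }
  a <- pdb$atom
  role <- .assign_roles(a$resid, water_resnames, ion_resnames, lipid_resnames)
  elem <- a$elesy
  need <- is.na(elem) | elem == ""
  if (any(need)) elem[need] <- .guess_element(a$elety[need], a$resid[need],
                                              role[need])
  chain <- a$chain; chain[is.na(chain)] <- " "
  atoms <- data.frame(atom_id = seq_len(nrow(a)), atom_name = a$elety,
                      element = elem, residue_name = a$resid,
                      residue_number = a$resno, chain_id = chain,
                      role = role, stringsAsFactors = FALSE)
  top <- topology(atoms)
  coords <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  if (nrow(coords) != nrow(atoms)) stop("coordinate/atom count mismatch")
  if (!quiet) message("load_model: ", nrow(atoms), " atoms (", fmt, ") from ",
                      basename(path))
  structure(list(topology = top, coords = coords, format = fmt),
            class = "clc_model")
}

#' @export
print.clc_model <- function(x, ...) {
  cat("<clc_model> ", n_atoms(x), " atoms, format ", x$format, "\n", sep = "")
  invisible(x)
}

#' Write a topology + coordinates (or multi-frame trajectory) as PDB
#'
#' Fixed-width ATOM/HETATM records; multiple frames are wrapped in
#' MODEL/ENDMDL blocks so the file round-trips through [load_trajectory()].
#'
#' @param topology \code{clc_topology}.
#' @param coords n_atoms x 3 matrix, or n_frames x n_atoms x 3 array.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(topology, coords, path) {
  a <- topology$atoms
  if (is.matrix(coords)) coords <- array(coords, c(1, dim(coords)))
  stopifnot(dim(coords)[2] == nrow(a), dim(coords)[3] == 3)
  rec <- ifelse(a$role == "protein", "ATOM  ", "HETATM")
  nm <- ifelse(nchar(a$atom_name) < 4, sprintf(" %-3s", a$atom_name),
               sprintf("%-4s", a$atom_name))
  con <- file(path, "w")
  on.exit(close(con))
  n_frames <- dim(coords)[1]
  for (f in seq_len(n_frames)) {
    if (n_frames > 1) writeLines(sprintf("MODEL     %4d", f), con)
    lines <- sprintf("%s%5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, a$atom_id %% 100000, nm, a$residue_name,
                     a$chain_id, a$residue_number %% 10000,
                     coords[f, , 1], coords[f, , 2], coords[f, , 3],
                     1.00, 0.00, a$element)
    writeLines(lines, con)
    if (n_frames > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
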