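# Core data model: structures, trajectories, atom selections.
# Internal length unit is nm; PDB files are read/written in Angstrom.

# Standard atomic masses (amu) keyed by element symbol.
.element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
  S = 32.06, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  "NA" = 22.990, K = 39.098, MG = 24.305, CA = 40.078, ZN = 65.38,
  FE = 55.845, MN = 54.938, CU = 63.546
)

.amino_acids <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HID", "HIE", "HIP", "CYX", "ASH", "GLH", "LYN"
)

.nucleic_acids <- c(
  "DA", "DT", "DG", "DC", "DU", "A", "U", "G", "C", "T",
  "DA5", "DT5", "DG5", "DC5", "DA3", "DT3", "DG3", "DC3",
  "A5", "U5", "G5", "C5", "A3", "U3", "G3", "C3", "RA", "RU", "RG", "RC"
)

.backbone_names <- c("N", "CA", "C", "O", "OXT")
.backbone_h     <- c("H", "HA", "HA2", "HA3", "H1", "H2", "H3")

# Derive an element symbol from a PDB atom name (e.g. "OP1" -> "O",
# "MG" -> "MG", "1HG1"/"HG11" -> "H").
.element_from_name <- function(name) {
  vapply(name, function(nm) {
    nm <- toupper(gsub("[^A-Za-z0-9]", "", nm))
    if (nm %in% names(.element_masses)) return(nm)
    # strip leading digits (old-style hydrogen names like 1HG1)
    core <- sub("^[0-9]+", "", nm)
    first <- substr(core, 1, 1)
    if (first %in% c("H", "C", "N", "O", "P", "S", "F", "K", "I")) first
    else if (substr(core, 1, 2) %in% names(.element_masses)) substr(core, 1, 2)
    else first
  }, character(1), USE.NAMES = FALSE)
}

.mass_from_element <- function(element, atom_name = element) {
  m <- .element_masses[toupper(element)]
  bad <- is.na(m)
  if (any(bad)) {
    warning("unknown element(s) ", paste(unique(atom_name[bad]), collapse = ", "),
            "; deriving element from atom name")
    el2 <- .element_from_name(atom_name[bad])
    m[bad] <- .element_masses[el2]
    if (anyNA(m)) stop("cannot assign masses for atoms: ",
                       paste(unique(atom_name[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Construct a molecular structure model
#'
#' A `structure_model` holds per-atom identity (name, element, residue,
#' chain), masses, optional partial charges, and coordinates in nm. It is
#' the basis for all atom selections and geometric analyses.
#'
#' @param atoms data.frame with columns `atom_id`, `atom_name`, `element`,
#'   `residue_number`, `residue_name`, `chain_id`, `mass` and optionally
#'   `charge`. Missing `element`/`mass` are derived from atom names.
#' @param xyz numeric matrix, n_atoms x 3, coordinates in nm.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  stopifnot(ncol(xyz) == 3, nrow(xyz) == nrow(atoms))
  if (is.null(atoms$element) || any(is.na(atoms$element)) || any(atoms$element == ""))
    atoms$element <- .element_from_name(atoms$atom_name)
  if (is.null(atoms$mass) || anyNA(atoms$mass))
    atoms$mass <- .mass_from_element(atoms$element, atoms$atom_name)
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  if (anyDuplicated(atoms$atom_id)) stop("atom_ids must be unique")
  if (any(atoms$mass <= 0)) stop("masses must be positive")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  rownames(xyz) <- NULL
  structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
                 xyz = xyz),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain_id, x$atoms$residue_number))),
      "residues,", length(unique(x$atoms$chain_id)), "chain(s)\n")
  invisible(x)
}

#' Load a structure (or multi-model ensemble) from a PDB file
#'
#' Coordinates are converted from Angstrom to nm. Masses are assigned from
#' the element (taken from the PDB element column when present, otherwise
#' derived from the atom name with a warning).
#'
#' @param path path to a PDB file.
#' @param multi if `TRUE` and the file holds several MODEL records, return a
#'   [trajectory_ensemble()] instead of a single structure.
#' @param frame_interval frame spacing in ps for `multi = TRUE`.
#' @param replicate_id replicate label for `multi = TRUE`.
#' @return A `structure_model`, or a `trajectory_ensemble` when
#'   `multi = TRUE`.
#' @export
load_structure <- function(path, multi = FALSE, frame_interval = 1,
                           replicate_id = 1L) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, multi = multi, verbose = FALSE)
  a <- pdb$atom
  element <- if (!is.null(a$elesy)) trimws(a$elesy) else ""
  element[is.na(element)] <- ""
  if (any(element == "")) {
    miss <- element == ""
    element[miss] <- .element_from_name(a$elety[miss])
  }
  atoms <- data.frame(
    atom_id        = a$eleno,
    atom_name      = trimws(a$elety),
    element        = toupper(element),
    residue_number = a$resno,
    residue_name   = trimws(a$resid),
    chain_id       = ifelse(is.na(a$chain) | a$chain == "", " ", a$chain),
    stringsAsFactors = FALSE
  )
  atoms$mass <- .mass_from_element(atoms$element, atoms$atom_name)
  xyz1 <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE) / 10
  ref <- structure_model(atoms, xyz1)
  nmod <- nrow(pdb$xyz)
  if (multi && nmod > 1) {
    frames <- array(0, dim = c(nrow(atoms), 3, nmod))
    for (i in seq_len(nmod))
      frames[, , i] <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE) / 10
    return(trajectory_ensemble(ref, frames, frame_interval = frame_interval,
                               replicate_id = replicate_id,
                               source_label = basename(path)))
  }
  ref
}

#' Write a structure or trajectory to a PDB file
#'
#' Coordinates are written in Angstrom. Multi-frame inputs produce one MODEL
#' record per frame, readable back with `load_structure(multi = TRUE)`.
#'
#' @param x a `structure_model` or `trajectory_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "trajectory_ensemble")) {
    ref <- x$reference
    xyz <- t(apply(x$frames, 3, function(f) as.vector(t(f)) * 10))
  } else {
    ref <- x
    xyz <- matrix(as.vector(t(ref$xyz)) * 10, nrow = 1)
  }
  a <- ref$atoms
  bio3d::write.pdb(
    file = path, xyz = xyz, type = "ATOM",
    resno = a$residue_number, resid = a$residue_name,
    eleno = a$atom_id, elety = a$atom_name, chain = a$chain_id,
    elesy = a$element
  )
  invisible(path)
}

#' Construct a trajectory ensemble
#'
#' An ordered series of coordinate frames (nm) over a fixed reference
#' topology, with the frame spacing in ps and a replicate label. Replicates
#' of the same system are separate ensembles sharing a reference.
#'
#' @param reference a [structure_model()].
#' @param frames numeric array n_atoms x 3 x n_frames (nm), or a list of
#'   n_atoms x 3 matrices.
#' @param frame_interval time between frames, ps.
#' @param replicate_id integer replicate label.
#' @param source_label free-text provenance string.
#' @return An object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(reference, frames, frame_interval = 1,
                                replicate_id = 1L, source_label = "") {
  stopifnot(inherits(reference, "structure_model"), frame_interval > 0)
  if (is.list(frames))
    frames <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  stopifnot(length(dim(frames)) == 3, dim(frames)[2] == 3)
  if (dim(frames)[1] != nrow(reference$atoms))
    stop("frame atom count does not match reference")
  structure(list(reference = reference, frames = frames,
                 frame_interval = frame_interval,
                 replicate_id = as.integer(replicate_id),
                 source_label = source_label),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("trajectory_ensemble:", n_frames(x), "frames x",
      dim(x$frames)[1], "atoms, dt =", x$frame_interval, "ps, replicate",
      x$replicate_id, "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory_ensemble`.
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' Extract one frame as an n x 3 coordinate matrix (nm)
#' @param traj a `trajectory_ensemble`.
#' @param i frame index.
#' @export
get_frame <- function(traj, i) traj$frames[, , i, drop = TRUE]

#' Read a trajectory from disk
#'
#' Supports multi-model PDB natively and DCD binary trajectories; frame
#' coordinates are stored in nm.
#'
#' @param path trajectory file (`.pdb` with MODEL records, or `.dcd`).
#' @param topology for DCD input, a PDB file providing the atom records.
#' @inheritParams load_structure
#' @return A [trajectory_ensemble()].
#' @export
load_trajectory <- function(path, topology = NULL, frame_interval = 1,
                            replicate_id = 1L) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent"))
    return(load_structure(path, multi = TRUE, frame_interval = frame_interval,
                          replicate_id = replicate_id))
  if (ext == "dcd") {
    if (is.null(topology)) stop("DCD input requires a PDB topology file")
    ref <- load_structure(topology)
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    frames <- array(0, dim = c(nrow(ref$atoms), 3, nrow(xyz)))
    for (i in seq_len(nrow(xyz)))
      frames[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10
    return(trajectory_ensemble(ref, frames, frame_interval, replicate_id,
                               source_label = basename(path)))
  }
  stop("unsupported trajectory format: .", ext,
       " (supported: multi-model PDB, DCD)")
}
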