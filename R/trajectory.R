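# Trajectory container: a static topology table plus an atoms x 3 x frames
# coordinate array. All coordinates are Angstroms, all angles degrees,
# package-wide.

#' Construct a trajectory object
#'
#' An `xtraj` bundles a per-atom topology table with coordinates for one or
#' more frames sharing that topology (the in-memory form of a single- or
#' multi-MODEL PDB file).
#'
#' @param topology `data.frame` with columns `serial` (integer),
#'   `atom_name`, `residue_name` (character), `residue_number` (integer),
#'   `chain_id`, `element` (character). An optional numeric `charge`
#'   column carries per-atom partial charges for extra-point bookkeeping.
#' @param coords Numeric array of dimension `c(n_atoms, 3, n_frames)`, or
#'   an `n_atoms x 3` matrix for a single frame. Angstroms.
#' @return An object of class `xtraj`.
#' @export
xtraj <- function(topology, coords) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(is.data.frame(topology), is.array(coords), length(dim(coords)) == 3L)
  required <- c("serial", "atom_name", "residue_name", "residue_number",
                "chain_id", "element")
  missing_cols <- setdiff(required, names(topology))
  if (length(missing_cols))
    stop("topology lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (dim(coords)[1] != nrow(topology))
    stop("topology error: coords have ", dim(coords)[1], " atoms but topology has ",
         nrow(topology))
  if (dim(coords)[2] != 3L) stop("coords must have 3 spatial columns")
  if (dim(coords)[3] < 1L) stop("trajectory must have at least one frame")
  if (!all(is.finite(coords))) stop("non-finite coordinates in trajectory")
  rownames(topology) <- NULL
  structure(list(topology = topology, coords = coords), class = "xtraj")
}

#' @export
print.xtraj <- function(x, ...) {
  cat("<xtraj> ", n_atoms(x), " atoms, ", n_frames(x), " frame(s)\n", sep = "")
  res <- unique(paste0(x$topology$residue_name, x$topology$residue_number))
  cat("  residues: ", paste(utils::head(res, 8), collapse = " "),
      if (length(res) > 8) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj An `xtraj`.
#' @return Integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Extract one frame's coordinates
#' @param traj An `xtraj`.
#' @param i Frame index (1-based).
#' @return `n_atoms x 3` numeric matrix in Angstroms.
#' @export
frame_coords <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range: ", i)
  m <- traj$coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

standard_aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")
water_resnames <- c("HOH", "WAT", "TIP", "TIP3", "SOL")

# canonical capitalization for an upper-case symbol, NA if unrecognized
canonical_element <- function(sym) {
  known <- c(names(bondi_radii()), "Se", "Fe", "Zn", "Mg", "Mn", "Na", "K",
             "Ca", "Cu", "Ni", "Co", "Cd", "Hg", "Si", "B", "Li")
  m <- match(toupper(sym), toupper(known))
  ifelse(is.na(m), NA_character_, known[m])
}

# PDB v3.3 element inference from the atom-name column. Two-letter symbols
# (Cl, Br, Fe...) are right-justified into columns 13-14, so in hetero
# residues a leading two-letter match wins; in standard amino acids and
# waters names like "CA"/"CD1" are carbons and "HZ"/"1HB" hydrogens.
infer_element <- function(atom_name, residue_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  if (!nzchar(nm)) return(NA_character_)
  protein_like <- toupper(residue_name) %in% c(standard_aa3, water_resnames)
  if (grepl("^[0-9]", trimws(atom_name)) && substr(nm, 1, 1) == "H") return("H")
  if (protein_like) {
    el <- canonical_element(substr(nm, 1, 1))
    return(if (is.na(el)) NA_character_ else el)
  }
  two <- c("CL", "BR", "SE", "FE", "ZN", "MG", "MN", "NA", "CA", "CU", "NI",
           "CO", "CD", "HG", "SI", "LI")
  if (nchar(nm) >= 2 && substr(nm, 1, 2) %in% two)
    return(canonical_element(substr(nm, 1, 2)))
  canonical_element(substr(nm, 1, 1))
}

#' Read a PDB structure or trajectory
#'
#' Parses a single- or multi-MODEL PDB file into an [xtraj()]. Each MODEL
#' block becomes one frame; a file without MODEL records yields one frame.
#' The element is taken from columns 77-78 when present, otherwise
#' inferred from the atom name following PDB v3.3 conventions (residue
#' context disambiguates names such as "CA"). Alternate locations other
#' than "A"/blank are dropped; waters and hydrogens are retained so that
#' atoms like a lysine HZ remain addressable.
#'
#' @param path Path to a PDB file, or a directory of sequentially numbered
#'   single-model PDB files forming one trajectory.
#' @return An [xtraj()].
#' @export
read_pdb <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE))
    if (!length(files)) stop("no .pdb files in directory ", path)
    trajs <- lapply(files, read_pdb)
    na <- vapply(trajs, n_atoms, 1L)
    if (length(unique(na)) != 1L)
      stop("topology error: atom counts differ across files (",
           paste(unique(na), collapse = ", "), ")")
    coords <- array(unlist(lapply(trajs, function(t) t$coords)),
                    dim = c(na[1], 3, sum(vapply(trajs, n_frames, 1L))))
    return(xtraj(trajs[[1]]$topology, coords))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  prescan_pdb(lines)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elesy <- trimws(as.character(at$elesy))
  element <- canonical_element(elesy)
  needs <- is.na(element) | !nzchar(elesy) | is.na(elesy)
  if (any(needs)) {
    element[needs] <- mapply(infer_element, at$elety[needs], at$resid[needs],
                             USE.NAMES = FALSE)
  }
  chain <- as.character(at$chain)
  chain[is.na(chain)] <- ""
  topology <- data.frame(
    serial = as.integer(at$eleno),
    atom_name = as.character(at$elety),
    residue_name = as.character(at$resid),
    residue_number = as.integer(at$resno),
    chain_id = chain,
    element = element,
    stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  natm <- nrow(topology)
  coords <- array(NA_real_, dim = c(natm, 3, nrow(xyz)))
  for (f in seq_len(nrow(xyz)))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  xtraj(topology, coords)
}

# Validate fixed-width records before handing the file to the parser:
# malformed coordinate fields get a line-numbered error, and MODEL blocks
# with unequal (altloc-filtered) atom counts a topology error.
prescan_pdb <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records found")
  for (ln in which(is_atom)) {
    l <- lines[ln]
    if (nchar(l) < 54)
      stop("parse error at line ", ln, ": ATOM/HETATM record shorter than 54 columns")
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                         substr(l, 47, 54))))
    if (any(is.na(xyz)))
      stop("parse error at line ", ln, ": unparseable coordinate field")
  }
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1L) {
    ends <- which(startsWith(lines, "ENDMDL"))
    if (length(ends) != length(model_starts))
      stop("parse error: MODEL/ENDMDL records unbalanced")
    counts <- mapply(function(a, b) {
      blk <- lines[a:b]
      keep <- substr(blk, 1, 6) %in% c("ATOM  ", "HETATM") &
        substr(blk, 17, 17) %in% c(" ", "", "A")
      sum(keep)
    }, model_starts, ends)
    if (length(unique(counts)) != 1L)
      stop("topology error: MODEL blocks have differing atom counts (",
           paste(counts, collapse = ", "), ")")
  }
  invisible(TRUE)
}

#' Write a trajectory as a (multi-MODEL) PDB file
#'
#' Coordinates are serialized at the fixed PDB precision of 3 decimals;
#' a trajectory with more than one frame is written as MODEL/ENDMDL
#' blocks. Element symbols go to columns 77-78 so a round trip through
#' [read_pdb()] preserves names, residues and elements.
#'
#' @param traj An [xtraj()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(traj, path) {
  top <- traj$topology
  nf <- n_frames(traj)
  xyz <- matrix(NA_real_, nrow = nf, ncol = 3L * n_atoms(traj))
  for (f in seq_len(nf)) xyz[f, ] <- as.vector(t(frame_coords(traj, f)))
  elesy <- toupper(top$element)
  elesy[is.na(elesy)] <- ""
  bio3d::write.pdb(file = path, xyz = xyz,
                   eleno = top$serial, elety = top$atom_name,
                   resid = top$residue_name, resno = top$residue_number,
                   chain = ifelse(nzchar(top$chain_id), top$chain_id, " "),
                   elesy = elesy)
  invisible(path)
}
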