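# Frame- and trajectory-level halogen-bond detection: enumerate acceptor
# atoms (protein O/N/S) and aromatic rings, test every donor against
# every acceptor, and collect observations.

halogen_elements <- c("F", "Cl", "Br", "I")

# Ring atom templates per aromatic residue. TRP contributes two rings
# (pyrrole and benzene), tested independently: its two pi faces are
# distinct acceptors.
ring_templates <- list(
  PHE = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(ring = c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(pyrrole = c("CG", "CD1", "NE1", "CE2", "CD2"),
             benzene = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

residue_key <- function(top, idx) {
  paste0(top$residue_name[idx], top$residue_number[idx],
         ifelse(nzchar(top$chain_id[idx]), paste0(".", top$chain_id[idx]), ""))
}

#' Enumerate aromatic rings in a topology
#'
#' Finds every ring of the configured aromatic residues whose template
#' atoms are all present; rings with missing atoms are skipped with a
#' warning (common for stripped or partially resolved residues).
#'
#' @param traj An [xtraj()].
#' @param aromatic_residues Residue names to scan.
#' @param exclude Atom indices whose residues are excluded (e.g. the
#'   ligand itself).
#' @return List of ring descriptors: `ring_id`, `residue`, `resname`,
#'   `resid`, `chain`, `atom_indices`.
#' @export
enumerate_rings <- function(traj, aromatic_residues = c("PHE", "TYR", "HIS", "TRP"),
                            exclude = integer(0)) {
  top <- traj$topology
  excl_res <- unique(paste(top$residue_number[exclude], top$chain_id[exclude]))
  rings <- list()
  cand <- which(toupper(top$residue_name) %in% toupper(aromatic_residues))
  if (!length(cand)) return(rings)
  groups <- split(cand, paste(top$residue_number[cand], top$chain_id[cand]))
  for (g in names(groups)) {
    if (g %in% excl_res) next
    idx <- groups[[g]]
    resname <- toupper(top$residue_name[idx[1]])
    tmpl <- ring_templates[[resname]]
    if (is.null(tmpl)) next
    for (tname in names(tmpl)) {
      m <- match(tmpl[[tname]], toupper(top$atom_name[idx]))
      if (anyNA(m)) {
        warning("ring skipped: ", residue_key(top, idx[1]), " (", tname,
                ") is missing atom(s) ",
                paste(tmpl[[tname]][is.na(m)], collapse = ","))
        next
      }
      rings[[length(rings) + 1L]] <- list(
        ring_id = paste0(residue_key(top, idx[1]), ":", tname),
        residue = residue_key(top, idx[1]),
        resname = resname,
        resid = top$residue_number[idx[1]],
        chain = top$chain_id[idx[1]],
        atom_indices = idx[m])
    }
  }
  rings
}

#' Auto-discover donor carbon-halogen pairs in a ligand
#'
#' Any halogen (F, Cl, Br, I) among the ligand atoms bonded to a carbon
#' at < 2.1 Angstroms (in the first frame) forms a donor pair.
#'
#' @param traj An [xtraj()].
#' @param ligand Ligand atoms: selection expression, `atom_selection`, or
#'   indices.
#' @return List of integer pairs `c(carbon_index, halogen_index)`.
#' @export
find_donors <- function(traj, ligand) {
  lig <- resolve_selection(traj, ligand, "ligand")
  top <- traj$topology
  xyz <- frame_coords(traj, 1)
  xs <- lig[top$element[lig] %in% halogen_elements]
  donors <- list()
  for (x in xs) {
    carbons <- lig[top$element[lig] == "C"]
    if (!length(carbons)) next
    d <- sqrt(colSums((t(xyz[carbons, , drop = FALSE]) - xyz[x, ])^2))
    j <- which.min(d)
    if (d[j] < 2.1)
      donors[[length(donors) + 1L]] <- c(carbons[j], x)
  }
  donors
}

#' Detect halogen bonds in one frame
#'
#' Runs [point_xbond_check()] over every (donor, acceptor-atom) pair and
#' [pi_xbond_check()] over every (donor, ring) pair. Acceptor atoms are
#' all O/N/S atoms (backbone and side chain) outside the ligand's own
#' residue; water acceptors are excluded unless `criteria$include_water`.
#' Rings come from the configured aromatic residues via templates. For pi
#' bonds, the distance from the halogen to the nearest ring atom is also
#' reported alongside the centroid distance.
#'
#' @param traj An [xtraj()].
#' @param frame Frame index.
#' @param donors List of `c(carbon_index, halogen_index)` pairs, e.g.
#'   from [find_donors()].
#' @param criteria [xbond_criteria()].
#' @param rings Optional precomputed ring list from [enumerate_rings()].
#' @param warn_unbonded Warn when a donor pair is further apart than
#'   2.1 Angstroms (pair still processed).
#' @return `data.frame` of observations: `frame`, `bond_type`
#'   (`"point"`/`"pi"`), `donor_carbon`, `halogen`, `acceptor_index`,
#'   `ring_id`, `acceptor_residue`, `acceptor_resname`, `acceptor_resid`,
#'   `distance`, `beta`, `alpha`, `theta`, `d_nearest_atom`.
#' @export
detect_frame_xbonds <- function(traj, frame = 1L, donors,
                                criteria = xbond_criteria(),
                                rings = NULL, warn_unbonded = TRUE) {
  top <- traj$topology
  xyz <- frame_coords(traj, frame)
  stopifnot(length(donors) >= 1L)
  lig_atoms <- unlist(donors)
  lig_res <- unique(paste(top$residue_number[lig_atoms], top$chain_id[lig_atoms]))
  res_tag <- paste(top$residue_number, top$chain_id)

  acc <- which(top$element %in% criteria$acceptor_elements &
                 !(res_tag %in% lig_res))
  if (!criteria$include_water)
    acc <- acc[!toupper(top$residue_name[acc]) %in% water_resnames]

  if (is.null(rings))
    rings <- enumerate_rings(traj, criteria$aromatic_residues, exclude = lig_atoms)

  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- list(...)
  for (dp in donors) {
    ci <- dp[1]; xi <- dp[2]
    if (warn_unbonded && vnorm(xyz[xi, ] - xyz[ci, ]) > 2.1)
      warning("donor pair ", ci, "-", xi, " further apart than 2.1 A in frame ",
              frame, "; processed anyway")
    for (ai in acc) {
      hit <- point_xbond_check(xyz[ci, ], xyz[xi, ], xyz[ai, ],
                               top$element[xi], top$element[ai], criteria)
      if (!is.null(hit))
        add(frame = frame, bond_type = "point", donor_carbon = ci, halogen = xi,
            acceptor_index = ai, ring_id = NA_character_,
            acceptor_residue = residue_key(top, ai),
            acceptor_resname = top$residue_name[ai],
            acceptor_resid = top$residue_number[ai],
            distance = hit$distance, beta = hit$beta,
            alpha = NA_real_, theta = NA_real_, d_nearest_atom = NA_real_)
    }
    for (rg in rings) {
      pl <- ring_plane(xyz[rg$atom_indices, , drop = FALSE])
      hit <- pi_xbond_check(xyz[ci, ], xyz[xi, ], pl, criteria)
      if (!is.null(hit)) {
        dn <- min(sqrt(colSums((t(xyz[rg$atom_indices, , drop = FALSE]) - xyz[xi, ])^2)))
        add(frame = frame, bond_type = "pi", donor_carbon = ci, halogen = xi,
            acceptor_index = NA_integer_, ring_id = rg$ring_id,
            acceptor_residue = rg$residue, acceptor_resname = rg$resname,
            acceptor_resid = rg$resid,
            distance = hit$distance, beta = NA_real_,
            alpha = hit$alpha, theta = hit$theta, d_nearest_atom = dn)
      }
    }
  }
  if (!length(rows)) return(empty_observations())
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

empty_observations <- function() {
  data.frame(frame = integer(0), bond_type = character(0),
             donor_carbon = integer(0), halogen = integer(0),
             acceptor_index = integer(0), ring_id = character(0),
             acceptor_residue = character(0), acceptor_resname = character(0),
             acceptor_resid = integer(0), distance = numeric(0),
             beta = numeric(0), alpha = numeric(0), theta = numeric(0),
             d_nearest_atom = numeric(0), stringsAsFactors = FALSE)
}

#' Detect halogen bonds across all frames of a trajectory
#'
#' @inheritParams detect_frame_xbonds
#' @param ligand Used to auto-discover donors when `donors` is `NULL`.
#' @return Observations `data.frame` (see [detect_frame_xbonds()]) over
#'   all frames.
#' @export
detect_xbonds <- function(traj, donors = NULL, ligand = NULL,
                          criteria = xbond_criteria()) {
  if (is.null(donors)) {
    if (is.null(ligand)) stop("provide donors or a ligand selection")
    donors <- find_donors(traj, ligand)
  }
  if (!length(donors)) stop("no donor carbon-halogen pairs found")
  lig_atoms <- unlist(donors)
  rings <- enumerate_rings(traj, criteria$aromatic_residues, exclude = lig_atoms)
  out <- lapply(seq_len(n_frames(traj)), function(f)
    detect_frame_xbonds(traj, f, donors, criteria, rings = rings,
                        warn_unbonded = (f == 1L)))
  do.call(rbind, out)
}

#' Write halogen-bond observations to CSV
#'
#' One row per observation (frame, type, donor, acceptor, distance and
#' angles).
#'
#' @param observations Output of [detect_xbonds()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_observations_csv <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE)
  invisible(path)
}
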