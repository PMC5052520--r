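# Sigma-hole extra-point (EP) placement: the positive extra point that
# represents the halogen's sigma-hole in modified force fields sits on
# the extension of the C-X bond axis, beyond the halogen, at a fixed
# offset (1.90 Angstroms by default). The EP charge itself comes from an
# external parameterization (e.g. RESP fitting) and is therefore a
# required user input; charge conservation is enforced by subtracting
# the EP charge from the parent halogen.

#' Place a sigma-hole extra point
#'
#' Computes the extra-point position `ep = x + offset * (x - c)/|x - c|`:
#' collinear with the C-X bond, on the distal side of the halogen, at
#' exactly `offset` Angstroms from it.
#'
#' @param c_pos Donor carbon position (3-vector, Angstroms).
#' @param x_pos Halogen position.
#' @param offset Halogen-to-EP distance in Angstroms (default 1.90).
#' @return Numeric 3-vector: the EP position.
#' @export
#' @examples
#' place_ep(c(0, 0, 0), c(1.70, 0, 0))  # c(3.60, 0, 0)
place_ep <- function(c_pos, x_pos, offset = 1.90) {
  stopifnot(offset > 0)
  v <- x_pos - c_pos
  nv <- vnorm(v)
  if (nv < 1e-12)
    stop("degenerate geometry: carbon and halogen positions coincide")
  x_pos + offset * v / nv
}

#' Append sigma-hole extra points to a structure
#'
#' For every halogen in the ligand bonded to a carbon (< 2.1 Angstroms),
#' appends one EP pseudo-atom (atom name `EP1`, `EP2`, ..., residue of
#' the ligand, element marked `EP`) positioned by [place_ep()] in every
#' frame. When the topology carries a `charge` column, the EP receives
#' `ep_charge` and the parent halogen's charge is reduced by `ep_charge`,
#' so the molecular total is conserved exactly.
#'
#' @param traj An [xtraj()].
#' @param ligand Ligand selection (expression, `atom_selection`, or
#'   indices).
#' @param ep_charge EP partial charge in elementary charge units
#'   (required; no default is shipped because the value comes from an
#'   external charge derivation).
#' @param offset Halogen-to-EP distance, Angstroms. Default 1.90.
#' @return A new [xtraj()] with the EP atoms appended; attribute
#'   `ep_parents` records each EP's parent halogen index.
#' @export
apply_ep <- function(traj, ligand, ep_charge, offset = 1.90) {
  if (missing(ep_charge) || !is.numeric(ep_charge))
    stop("ep_charge is required (elementary charge units)")
  donors <- find_donors(traj, ligand)
  lig <- resolve_selection(traj, ligand, "ligand")
  top <- traj$topology
  xs_all <- lig[top$element[lig] %in% halogen_elements]
  placed <- vapply(donors, function(dp) dp[2], 1L)
  orphan <- setdiff(xs_all, placed)
  if (length(orphan))
    stop("connectivity error: halogen atom(s) ",
         paste(orphan, collapse = ","), " have no carbon within 2.1 A")
  if (!length(donors)) stop("ligand contains no bonded halogen")

  nf <- n_frames(traj)
  n_ep <- length(donors)
  new_top <- top
  has_charge <- "charge" %in% names(top)
  ep_rows <- lapply(seq_len(n_ep), function(i) {
    xi <- donors[[i]][2]
    row <- top[xi, , drop = FALSE]
    row$serial <- max(top$serial) + i
    row$atom_name <- paste0("EP", i)
    row$element <- "EP"
    if (has_charge) row$charge <- ep_charge
    row
  })
  new_top <- rbind(new_top, do.call(rbind, ep_rows))
  if (has_charge) {
    for (dp in donors)
      new_top$charge[dp[2]] <- new_top$charge[dp[2]] - ep_charge
  }
  coords <- array(NA_real_, dim = c(nrow(new_top), 3, nf))
  coords[seq_len(n_atoms(traj)), , ] <- traj$coords
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    for (i in seq_len(n_ep)) {
      dp <- donors[[i]]
      coords[n_atoms(traj) + i, , f] <- place_ep(xyz[dp[1], ], xyz[dp[2], ], offset)
    }
  }
  out <- xtraj(new_top, coords)
  attr(out, "ep_parents") <- vapply(donors, function(dp) dp[2], 1L)
  out
}

#' Remove extra-point pseudo-atoms
#'
#' Strips EP atoms appended by [apply_ep()] and restores the parent
#' halogen charges, recovering the original atom count and total charge.
#'
#' @param traj An [xtraj()] produced by [apply_ep()].
#' @return The trajectory without EP atoms.
#' @export
strip_ep <- function(traj) {
  top <- traj$topology
  is_ep <- !is.na(top$element) & top$element == "EP" &
    grepl("^EP[0-9]+$", top$atom_name)
  if (!any(is_ep)) return(traj)
  parents <- attr(traj, "ep_parents")
  keep <- which(!is_ep)
  new_top <- top[keep, , drop = FALSE]
  if ("charge" %in% names(top) && !is.null(parents)) {
    ep_charges <- top$charge[is_ep]
    for (i in seq_along(parents))
      new_top$charge[parents[i]] <- new_top$charge[parents[i]] + ep_charges[i]
  }
  xtraj(new_top, traj$coords[keep, , , drop = FALSE])
}

#' Write a per-atom charge table
#'
#' PDB files carry no partial-charge column with usable precision, so
#' charges travel in a sidecar CSV (atom serial, atom name, charge).
#'
#' @param traj An [xtraj()] whose topology has a `charge` column.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_charges_csv <- function(traj, path) {
  top <- traj$topology
  if (!"charge" %in% names(top)) stop("topology has no charge column")
  utils::write.csv(data.frame(serial = top$serial, atom_name = top$atom_name,
                              charge = top$charge),
                   path, row.names = FALSE)
  invisible(path)
}
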