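#' Bondi van der Waals radii
#'
#' Returns the default van der Waals radius table used for halogen-bond
#' distance cutoffs. Radii are the Bondi (1964) consensus values, in
#' Angstroms. With this table the pairwise sums for a chlorine donor are
#' Cl+O = 3.27, Cl+N = 3.30 and Cl+S = 3.55 Angstroms, the standard
#' distance criteria for C-Cl...Y halogen bonds.
#'
#' @return Named numeric vector mapping element symbols to radii in
#'   Angstroms. Covers H, C, N, O, F, P, S, Cl, Br and I.
#' @export
#' @examples
#' bondi_radii()[["Cl"]] + bondi_radii()[["O"]]  # 3.27
bondi_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
    P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)
}

#' Look up a van der Waals radius
#'
#' @param element Element symbol (case-sensitive, e.g. `"Cl"`).
#' @param table Named numeric vector of radii in Angstroms; defaults to
#'   [bondi_radii()].
#' @return Radius in Angstroms.
#' @export
#' @examples
#' vdw_radius("Cl")  # 1.75
vdw_radius <- function(element, table = bondi_radii()) {
  stopifnot(is.numeric(table), all(table > 0))
  if (length(element) != 1L || is.na(element) || !element %in% names(table)) {
    stop("unknown element '", element, "'; known elements: ",
         paste(names(table), collapse = ", "), call. = FALSE)
  }
  unname(table[[element]])
}

#' Distance cutoff for a halogen/acceptor element pair
#'
#' The point-acceptor halogen-bond distance criterion: the sum of the van
#' der Waals radii of the two elements. Symmetric in its arguments.
#'
#' @param x,y Element symbols (halogen and acceptor, in either order).
#' @inheritParams vdw_radius
#' @return Cutoff distance in Angstroms.
#' @export
#' @examples
#' cutoff_for_pair("Cl", "O")  # 3.27
#' cutoff_for_pair("Cl", "S")  # 3.55
cutoff_for_pair <- function(x, y, table = bondi_radii()) {
  vdw_radius(x, table) + vdw_radius(y, table)
}
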