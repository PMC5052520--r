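#' Halogen-bond geometric criteria
#'
#' Bundles the thresholds for both halogen-bond types. A point
#' (C-X...Y) bond requires the X...Y distance strictly below the pair
#' cutoff (by default the Bondi vdW sum, e.g. Cl...O 3.27, Cl...N 3.30,
#' Cl...S 3.55 Angstroms) and the C-X...Y angle beta strictly above
#' `beta_min`. A pi (C-X...ring) bond requires the X...centroid distance
#' strictly below `pi_d_max`, the angle alpha between the ring normal and
#' the centroid-to-halogen vector strictly below `alpha_max`, and the
#' C-X...centroid angle theta strictly above `theta_min`.
#'
#' @param beta_min Minimum C-X...Y angle, degrees. Default 140.
#' @param pi_d_max Maximum X...ring-centroid distance, Angstroms. Default 4.2.
#' @param alpha_max Maximum angle between ring normal and centroid-to-X
#'   vector, degrees. Default 60.
#' @param theta_min Minimum C-X...centroid angle, degrees. Default 146.
#' @param acceptor_elements Elements accepted as point acceptors.
#' @param aromatic_residues Residue names whose rings are pi acceptors.
#' @param vdw_table Named radius table (Angstroms) used for pair cutoffs.
#' @param point_cutoffs Optional named list of per-pair overrides, names
#'   like `"Cl-O"`, values in Angstroms; pairs not listed fall back to
#'   the vdW sum.
#' @param include_water Treat water oxygens as acceptors. Default `FALSE`.
#' @return Object of class `xbond_criteria`.
#' @export
xbond_criteria <- function(beta_min = 140, pi_d_max = 4.2, alpha_max = 60,
                           theta_min = 146,
                           acceptor_elements = c("O", "N", "S"),
                           aromatic_residues = c("PHE", "TYR", "HIS", "TRP"),
                           vdw_table = bondi_radii(),
                           point_cutoffs = NULL,
                           include_water = FALSE) {
  stopifnot(beta_min > 0, beta_min < 180, theta_min > 0, theta_min < 180,
            alpha_max > 0, alpha_max <= 90, pi_d_max > 0,
            all(vdw_table > 0))
  if (!is.null(point_cutoffs)) {
    stopifnot(is.list(point_cutoffs) || is.numeric(point_cutoffs))
    if (any(unlist(point_cutoffs) <= 0)) stop("point cutoffs must be positive")
  }
  structure(list(beta_min = beta_min, pi_d_max = pi_d_max,
                 alpha_max = alpha_max, theta_min = theta_min,
                 acceptor_elements = acceptor_elements,
                 aromatic_residues = toupper(aromatic_residues),
                 vdw_table = vdw_table,
                 point_cutoffs = point_cutoffs,
                 include_water = include_water),
            class = "xbond_criteria")
}

# pair cutoff honoring per-pair overrides ("X-Y" or "Y-X" keys)
criteria_cutoff <- function(criteria, x, y) {
  pc <- criteria$point_cutoffs
  if (!is.null(pc)) {
    k1 <- paste0(x, "-", y); k2 <- paste0(y, "-", x)
    if (!is.null(pc[[k1]])) return(as.numeric(pc[[k1]]))
    if (!is.null(pc[[k2]])) return(as.numeric(pc[[k2]]))
  }
  cutoff_for_pair(x, y, criteria$vdw_table)
}

#' @export
print.xbond_criteria <- function(x, ...) {
  cat("Halogen-bond criteria\n")
  cat("  point (C-X...Y): d < vdW sum",
      if (!is.null(x$point_cutoffs)) " (with overrides)" else "",
      ", beta > ", x$beta_min, " deg; acceptors {",
      paste(x$acceptor_elements, collapse = ","), "}\n", sep = "")
  cat("  pi (C-X...ring): d < ", x$pi_d_max, " A, alpha < ", x$alpha_max,
      " deg, theta > ", x$theta_min, " deg; rings from ",
      paste(x$aromatic_residues, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Read criteria overrides from a key-value config file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a
#' comment. Recognized keys: `beta_min`, `pi_d_max`, `alpha_max`,
#' `theta_min`, and per-pair cutoffs written as element pairs, e.g.
#' `Cl-O = 3.27`.
#'
#' @param path Config file path.
#' @param base Criteria object to override; default [xbond_criteria()].
#' @return `xbond_criteria`.
#' @export
read_criteria_config <- function(path, base = xbond_criteria()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  overrides <- base$point_cutoffs %||% list()
  for (l in lines) {
    kv <- strsplit(l, "[=:]")[[1]]
    if (length(kv) != 2L) stop("bad config line: '", l, "'")
    key <- trimws(kv[1]); val <- as.numeric(trimws(kv[2]))
    if (is.na(val)) stop("non-numeric value in config line: '", l, "'")
    if (key %in% c("beta_min", "pi_d_max", "alpha_max", "theta_min")) {
      base[[key]] <- val
    } else if (grepl("^[A-Za-z]+-[A-Za-z]+$", key)) {
      overrides[[key]] <- val
    } else stop("unknown config key: '", key, "'")
  }
  if (length(overrides)) base$point_cutoffs <- overrides
  # re-validate through the constructor
  xbond_criteria(beta_min = base$beta_min, pi_d_max = base$pi_d_max,
                 alpha_max = base$alpha_max, theta_min = base$theta_min,
                 acceptor_elements = base$acceptor_elements,
                 aromatic_residues = base$aromatic_residues,
                 vdw_table = base$vdw_table,
                 point_cutoffs = base$point_cutoffs,
                 include_water = base$include_water)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
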