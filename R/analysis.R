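# Trajectory-level aggregation: labeled key-distance time series and
# mean +/- SD summaries (Table-style columns such as D_C8-SG, D_N1-HZ),
# per-residue halogen-bond occupancy, and the combined analysis report.

#' Define a labeled atom-pair distance
#'
#' @param label Label for the distance, e.g. `"D_C8-SG"`.
#' @param selection_a,selection_b Selections (expression strings,
#'   `atom_selection` objects or indices) each resolving to exactly one
#'   atom.
#' @return Object of class `distance_spec`.
#' @export
#' @examples
#' distance_spec("D_C8-SG", "resid 1 and name C8", "resid 169 and name SG")
distance_spec <- function(label, selection_a, selection_b) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  structure(list(label = label, selection_a = selection_a,
                 selection_b = selection_b), class = "distance_spec")
}

#' Per-frame distance time series
#'
#' Euclidean distance between the two selected atoms in every frame, in
#' frame order.
#'
#' @param traj An [xtraj()].
#' @param spec A [distance_spec()].
#' @return Object of class `dist_series`: list with `label` and numeric
#'   `values` (Angstroms, one per frame).
#' @export
distance_series <- function(traj, spec) {
  stopifnot(inherits(spec, "distance_spec"))
  a <- resolve_selection(traj, spec$selection_a,
                         paste0(spec$label, " selection A"), exactly_one = TRUE)
  b <- resolve_selection(traj, spec$selection_b,
                         paste0(spec$label, " selection B"), exactly_one = TRUE)
  d <- sqrt(colSums((traj$coords[a, , ] - traj$coords[b, , ])^2))
  structure(list(label = spec$label, values = as.numeric(d)),
            class = "dist_series")
}

#' Summarize a distance series as mean +/- SD
#'
#' The mean is the arithmetic mean over frames; the SD is the sample
#' standard deviation (n-1 denominator). With a single frame the SD is
#' reported as 0 with a warning.
#'
#' @param series A `dist_series` (from [distance_series()]) or bare
#'   numeric vector of distances.
#' @param label Label when `series` is a bare vector.
#' @return Object of class `dist_summary`: `label`, `mean`, `sd`,
#'   `n_frames`.
#' @export
summarize_series <- function(series, label = NULL) {
  if (inherits(series, "dist_series")) {
    values <- series$values
    label <- label %||% series$label
  } else {
    values <- as.numeric(series)
    label <- label %||% "distance"
  }
  if (!length(values)) stop("empty distance series")
  s <- if (length(values) == 1L) {
    warning("single-frame series: sd reported as 0")
    0
  } else stats::sd(values)
  structure(list(label = label, mean = mean(values), sd = s,
                 n_frames = length(values)), class = "dist_summary")
}

#' Construct a distance summary from known moments
#'
#' Builds a `dist_summary` directly from a reported mean +/- SD (e.g. a
#' published table row) for use in [screen_mutant()] without the
#' underlying trajectory.
#'
#' @param label Distance label.
#' @param mean,sd Mean and standard deviation, Angstroms.
#' @param n_frames Number of frames behind the summary.
#' @return `dist_summary`.
#' @export
dist_summary <- function(label, mean, sd = 0, n_frames = 1L) {
  stopifnot(sd >= 0, n_frames >= 1)
  structure(list(label = label, mean = mean, sd = sd,
                 n_frames = as.integer(n_frames)), class = "dist_summary")
}

#' @export
print.dist_summary <- function(x, digits = 2, ...) {
  cat(sprintf("%s: %.*f +/- %.*f A (n = %d frames)\n", x$label, digits,
              x$mean, digits, x$sd, x$n_frames))
  invisible(x)
}

#' @export
print.dist_series <- function(x, ...) {
  cat("<dist_series> ", x$label, ": ", length(x$values), " frames, mean ",
      sprintf("%.2f", mean(x$values)), " A\n", sep = "")
  invisible(x)
}

#' Per-residue halogen-bond occupancy
#'
#' For each acceptor residue, the fraction of frames in which at least
#' one halogen bond to that residue is observed. Multiple simultaneous
#' bonds to one residue in one frame count once (residue granularity).
#' Fractions are reported pooled over bond types (`type = "all"`) and
#' broken out per type.
#'
#' @param traj An [xtraj()].
#' @param donors Donor pairs (see [detect_xbonds()]); or `NULL` with
#'   `ligand` given.
#' @param criteria [xbond_criteria()].
#' @param ligand Ligand selection for donor auto-discovery.
#' @param observations Optional precomputed observation table; when given
#'   the detector is not re-run.
#' @return Object of class `occupancy_profile`: a `data.frame` with
#'   columns `residue`, `resname`, `resid`, `type`, `fraction`, plus
#'   attributes `n_frames` and `dominant` (the residue with the maximal
#'   pooled fraction).
#' @export
occupancy_profile <- function(traj, donors = NULL, criteria = xbond_criteria(),
                              ligand = NULL, observations = NULL) {
  nf <- n_frames(traj)
  if (nf < 1L) stop("empty trajectory")
  obs <- observations %||% detect_xbonds(traj, donors, ligand, criteria)
  tab <- empty_occupancy()
  if (nrow(obs)) {
    per_type <- unique(obs[, c("frame", "bond_type", "acceptor_residue",
                               "acceptor_resname", "acceptor_resid")])
    pooled <- unique(per_type[, c("frame", "acceptor_residue",
                                  "acceptor_resname", "acceptor_resid")])
    pooled$bond_type <- "all"
    both <- rbind(per_type, pooled[, names(per_type)])
    agg <- stats::aggregate(frame ~ acceptor_residue + acceptor_resname +
                              acceptor_resid + bond_type, data = both, FUN = length)
    tab <- data.frame(residue = agg$acceptor_residue,
                      resname = agg$acceptor_resname,
                      resid = agg$acceptor_resid,
                      type = agg$bond_type,
                      fraction = agg$frame / nf,
                      stringsAsFactors = FALSE)
    tab <- tab[order(tab$type != "all", -tab$fraction, tab$residue), ]
    rownames(tab) <- NULL
  }
  pooled_rows <- tab[tab$type == "all", , drop = FALSE]
  dominant <- if (nrow(pooled_rows)) pooled_rows$residue[which.max(pooled_rows$fraction)]
              else NA_character_
  structure(tab, class = c("occupancy_profile", "data.frame"),
            n_frames = nf, dominant = dominant)
}

empty_occupancy <- function() {
  data.frame(residue = character(0), resname = character(0),
             resid = integer(0), type = character(0), fraction = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat("Halogen-bond occupancy over", attr(x, "n_frames"), "frames\n")
  if (!nrow(x)) {
    cat("  (no halogen bonds observed)\n")
    return(invisible(x))
  }
  pooled <- x[x$type == "all", , drop = FALSE]
  for (i in seq_len(nrow(pooled)))
    cat(sprintf("  %-12s %6.2f%%\n", pooled$residue[i], 100 * pooled$fraction[i]))
  cat("  dominant partner:", attr(x, "dominant"), "\n")
  invisible(x)
}

#' Analyze a protein-ligand trajectory
#'
#' The main entry point: detects halogen bonds in every frame, computes
#' the per-residue occupancy profile, and summarizes each requested key
#' distance as mean +/- SD over frames — the quantities used to compare
#' enzyme-substrate complexes (e.g. nitrile carbon to catalytic cysteine
#' SG, nitrile nitrogen to catalytic lysine HZ).
#'
#' @param traj An [xtraj()].
#' @param distance_specs List of [distance_spec()] objects.
#' @param donors Donor pairs, or `NULL` to auto-discover from `ligand`.
#' @param ligand Ligand selection (expression, `atom_selection`, or
#'   indices).
#' @param criteria [xbond_criteria()].
#' @param label Label for this complex (e.g. `"WT-1a"`).
#' @return Object of class `xbond_analysis`: list with `label`,
#'   `summaries` (named list of `dist_summary`), `series` (named list of
#'   `dist_series`), `occupancy`, `observations`, `frame_counts` (number
#'   of observations per frame), `n_frames`, `criteria`.
#' @export
xbond_analysis <- function(traj, distance_specs = list(), donors = NULL,
                           ligand = NULL, criteria = xbond_criteria(),
                           label = "complex") {
  if (inherits(distance_specs, "distance_spec"))
    distance_specs <- list(distance_specs)
  obs <- detect_xbonds(traj, donors, ligand, criteria)
  occ <- occupancy_profile(traj, criteria = criteria, observations = obs)
  series <- lapply(distance_specs, function(sp) distance_series(traj, sp))
  names(series) <- vapply(distance_specs, function(sp) sp$label, "")
  summaries <- lapply(series, summarize_series)
  counts <- tabulate(obs$frame, nbins = n_frames(traj))
  structure(list(label = label, summaries = summaries, series = series,
                 occupancy = occ, observations = obs,
                 frame_counts = counts, n_frames = n_frames(traj),
                 criteria = criteria),
            class = "xbond_analysis")
}

#' @export
print.xbond_analysis <- function(x, ...) {
  cat("Halogen-bond analysis:", x$label, "(", x$n_frames, "frames )\n")
  for (s in x$summaries) print(s)
  cat("Observations:", nrow(x$observations), "(",
      sum(x$frame_counts > 0), "frames with >= 1 bond )\n")
  pooled <- x$occupancy[x$occupancy$type == "all", , drop = FALSE]
  if (nrow(pooled)) {
    top <- utils::head(pooled[order(-pooled$fraction), ], 5)
    cat("Top acceptor residues:\n")
    for (i in seq_len(nrow(top)))
      cat(sprintf("  %-12s %6.2f%%\n", top$residue[i], 100 * top$fraction[i]))
  }
  invisible(x)
}

#' @export
summary.xbond_analysis <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.xbond_analysis <- function(x, ...) {
  nser <- length(x$series)
  if (!nser) {
    plot(seq_along(x$frame_counts), x$frame_counts, type = "h",
         xlab = "frame", ylab = "halogen bonds", main = x$label, ...)
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(nser, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (s in x$series)
    plot(seq_along(s$values), s$values, type = "l", xlab = "frame",
         ylab = paste(s$label, "(A)"), main = x$label, ...)
  invisible(x)
}

#' Serialize an analysis to JSON and CSV
#'
#' Writes `report.json` (stable key order, schema-versioned),
#' `distances.csv` (frame, label, value), `occupancy.csv` (residue,
#' type, fraction) and `observations.csv` into a directory. Re-running
#' on identical input reproduces byte-identical JSON.
#'
#' @param x An `xbond_analysis`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path of the JSON report.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "xbond_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  report <- list(
    schema_version = "1.0",
    label = x$label,
    n_frames = x$n_frames,
    distance_summaries = lapply(x$summaries, function(s)
      list(label = s$label, mean = round(s$mean, 6), sd = round(s$sd, 6),
           n_frames = s$n_frames)),
    occupancy = lapply(seq_len(nrow(x$occupancy)), function(i)
      list(residue = x$occupancy$residue[i], type = x$occupancy$type[i],
           fraction = round(x$occupancy$fraction[i], 6))),
    dominant_partner = attr(x$occupancy, "dominant"),
    frame_observation_counts = x$frame_counts
  )
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  dist_rows <- do.call(rbind, lapply(x$series, function(s)
    data.frame(frame = seq_along(s$values), label = s$label,
               value = s$values, stringsAsFactors = FALSE)))
  if (is.null(dist_rows))
    dist_rows <- data.frame(frame = integer(0), label = character(0),
                            value = numeric(0))
  utils::write.csv(dist_rows, file.path(dir, "distances.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(x$occupancy),
                   file.path(dir, "occupancy.csv"), row.names = FALSE)
  write_observations_csv(x$observations, file.path(dir, "observations.csv"))
  invisible(json_path)
}
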