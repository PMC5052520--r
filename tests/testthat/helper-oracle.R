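# Independent brute-force oracles, deliberately implemented with
# different algorithms than the package (law-of-cosines angles, Newell
# polygon normals, grid-search plane fitting) so agreement is evidence,
# not tautology.

# angle at vertex b via the law of cosines
oracle_angle <- function(a, b, c) {
  u <- sqrt(sum((a - b)^2)); v <- sqrt(sum((c - b)^2)); w <- sqrt(sum((a - c)^2))
  acos(min(1, max(-1, (u^2 + v^2 - w^2) / (2 * u * v)))) * 180 / pi
}

# polygon normal by Newell's method (sum of successive cross products)
oracle_ring_normal <- function(pos) {
  n <- nrow(pos)
  acc <- c(0, 0, 0)
  for (i in seq_len(n)) {
    p <- pos[i, ]; q <- pos[i %% n + 1, ]
    acc <- acc + c(p[2] * q[3] - p[3] * q[2],
                   p[3] * q[1] - p[1] * q[3],
                   p[1] * q[2] - p[2] * q[1])
  }
  acc / sqrt(sum(acc^2))
}

# exhaustive grid search over plane normals (coarse sphere grid + local
# refinement) minimizing the sum of squared point-plane distances
oracle_plane_normal <- function(pos, step = 1) {
  centered <- sweep(pos, 2, colMeans(pos))
  best <- NULL; best_ss <- Inf
  for (th in seq(0, 180, by = step)) {
    for (ph in seq(0, 359, by = step * 2)) {
      n <- c(sin(th * pi / 180) * cos(ph * pi / 180),
             sin(th * pi / 180) * sin(ph * pi / 180),
             cos(th * pi / 180))
      ss <- sum((centered %*% n)^2)
      if (ss < best_ss) { best_ss <- ss; best <- n }
    }
  }
  best
}

# full-frame brute-force halogen-bond enumeration; returns a set of
# string keys for order-free comparison with the detector
oracle_detect_keys <- function(traj, frame, donors, criteria) {
  top <- traj$topology
  xyz <- frame_coords(traj, frame)
  keys <- character(0)
  lig_res <- unique(paste(top$residue_number[unlist(donors)],
                          top$chain_id[unlist(donors)]))
  waters <- c("HOH", "WAT", "TIP", "TIP3", "SOL")
  for (dp in donors) {
    ci <- dp[1]; xi <- dp[2]
    xe <- top$element[xi]
    for (ai in seq_len(nrow(top))) {
      if (!top$element[ai] %in% criteria$acceptor_elements) next
      if (paste(top$residue_number[ai], top$chain_id[ai]) %in% lig_res) next
      if (toupper(top$residue_name[ai]) %in% waters && !criteria$include_water) next
      d <- sqrt(sum((xyz[xi, ] - xyz[ai, ])^2))
      cut <- xbondr::cutoff_for_pair(xe, top$element[ai], criteria$vdw_table)
      if (d >= cut) next
      if (oracle_angle(xyz[ci, ], xyz[xi, ], xyz[ai, ]) <= criteria$beta_min) next
      keys <- c(keys, paste("point", xi, ai, sep = ":"))
    }
    # rings: walk every aromatic residue and template independently
    tmpl <- list(PHE = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
                 TYR = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
                 HIS = list(ring = c("CG", "ND1", "CD2", "CE1", "NE2")),
                 TRP = list(pyrrole = c("CG", "CD1", "NE1", "CE2", "CD2"),
                            benzene = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")))
    res_tags <- unique(paste(top$residue_number, top$chain_id)[
      toupper(top$residue_name) %in% criteria$aromatic_residues])
    for (rt in res_tags) {
      if (rt %in% lig_res) next
      idx <- which(paste(top$residue_number, top$chain_id) == rt)
      resname <- toupper(top$residue_name[idx[1]])
      for (tname in names(tmpl[[resname]])) {
        m <- match(tmpl[[resname]][[tname]], toupper(top$atom_name[idx]))
        if (anyNA(m)) next
        pos <- xyz[idx[m], , drop = FALSE]
        centroid <- colMeans(pos)
        d <- sqrt(sum((xyz[xi, ] - centroid)^2))
        if (d >= criteria$pi_d_max) next
        nrm <- oracle_ring_normal(sweep(pos, 2, centroid))
        cosa <- sum((xyz[xi, ] - centroid) * nrm) / d
        alpha <- acos(min(1, max(-1, cosa))) * 180 / pi
        alpha <- min(alpha, 180 - alpha)
        if (alpha >= criteria$alpha_max) next
        if (oracle_angle(xyz[ci, ], xyz[xi, ], centroid) <= criteria$theta_min) next
        keys <- c(keys, paste("pi", xi, rt, tname, sep = ":"))
      }
    }
  }
  sort(keys)
}

# detector output reduced to the same key set
detector_keys <- function(obs, traj) {
  if (!nrow(obs)) return(character(0))
  top <- traj$topology
  keys <- ifelse(obs$bond_type == "point",
                 paste("point", obs$halogen, obs$acceptor_index, sep = ":"),
                 paste("pi", obs$halogen,
                       paste(obs$acceptor_resid,
                             sub(".*\\.", "", sub(":.*", "", obs$ring_id))),
                       sub(".*:", "", obs$ring_id), sep = ":"))
  sort(keys)
}
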