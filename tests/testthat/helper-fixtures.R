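# Shared fixtures: rigid-motion helpers and randomized toy structures.

# random proper rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# apply a rigid transform (rotation R then translation t) to every frame
rigid_transform <- function(traj, R = random_rotation(),
                            t = rnorm(3, 0, 10)) {
  coords <- traj$coords
  for (f in seq_len(dim(coords)[3]))
    coords[, , f] <- coords[, , f] %*% t(R) + matrix(t, nrow = dim(coords)[1],
                                                    ncol = 3, byrow = TRUE)
  out <- xtraj(traj$topology, coords)
  attributes(out)$planted <- attr(traj, "planted")
  out
}

# randomized single-frame structure for round-trip tests: arbitrary
# names/residues, coordinates in a 40 A box
random_structure <- function(n = 25) {
  top <- data.frame(
    serial = seq_len(n),
    atom_name = sample(c("CA", "CB", "O", "N", "SG", "CL1", "OG1"), n, TRUE),
    residue_name = sample(c("ALA", "CYS", "SER", "LIG"), n, TRUE),
    residue_number = sort(sample.int(50, n, TRUE)),
    chain_id = sample(c("A", "B"), n, TRUE),
    element = NA_character_,
    stringsAsFactors = FALSE)
  top$element <- mapply(xbondr:::infer_element, top$atom_name, top$residue_name)
  xtraj(top, matrix(runif(3 * n, -20, 20), n, 3))
}

# random ~50-atom frame with a halogenated ligand, assorted protein
# acceptors and one complete PHE ring, packed so chance contacts occur
random_contact_frame <- function(seed) {
  set.seed(seed)
  lig_c <- runif(3, -2, 2)
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  lig_x <- lig_c + 1.74 * u
  n_prot <- 42
  elements <- sample(c("C", "N", "O", "S", "H"), n_prot, TRUE,
                     prob = c(0.35, 0.2, 0.25, 0.1, 0.1))
  prot_names <- ifelse(elements == "O", "O",
                ifelse(elements == "N", "N",
                ifelse(elements == "S", "SD", ifelse(elements == "H", "HB", "CB"))))
  prot_res <- sample(c("GLY", "MET", "SER", "ALA"), n_prot, TRUE)
  prot_xyz <- matrix(runif(3 * n_prot, -6, 6), n_prot, 3)
  # one PHE ring: jittered hexagon at a random pose near the ligand
  rc <- runif(3, -4, 4)
  R <- random_rotation()
  ang <- (0:5) * pi / 3
  ring <- t(vapply(ang, function(a)
    rc + as.vector(R %*% c(1.39 * cos(a), 1.39 * sin(a), 0)), numeric(3)))
  ring <- ring + matrix(rnorm(18, 0, 0.03), 6, 3)
  top <- data.frame(
    serial = 1:(2 + n_prot + 6),
    atom_name = c("C1", "CL1", prot_names, "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    residue_name = c("LIG", "LIG", prot_res, rep("PHE", 6)),
    residue_number = c(1L, 1L, 100L + seq_len(n_prot), rep(300L, 6)),
    chain_id = "A",
    element = c("C", "Cl", elements, rep("C", 6)),
    stringsAsFactors = FALSE)
  xtraj(top, rbind(lig_c, lig_x, prot_xyz, ring))
}
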