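# Synthetic toy active-site complexes with planted halogen-bond
# geometries and key-distance distributions. The generator emulates the
# statistical shape of an enzyme-substrate MD trajectory — a 1000-frame
# ensemble with a chloro-benzyl-cyanide-like ligand, point and ring
# acceptors, and catalytic Cys SG / Lys HZ pseudo-atoms — so the
# detector, occupancy statistics and screening rule can be validated
# against planted ground truth. Frames are placed decisively inside or
# outside the criteria (violations by >= 0.3 A or 10 deg), never near a
# boundary, so floating-point noise cannot flip a frame's class.

# run expr under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Describe a planted halogen-bond contact
#'
#' @param type `"point"` (C-X...Y to a backbone-oxygen pseudo-residue,
#'   GLY195 in the toy topology) or `"pi"` (C-X...ring to the PHE202
#'   ring).
#' @param distance Target X...acceptor (or X...centroid) distance in
#'   in-criteria frames, Angstroms.
#' @param beta Target C-X...Y angle (point type), degrees.
#' @param alpha,theta Target ring-normal and C-X...centroid angles (pi
#'   type), degrees.
#' @param fraction Fraction of frames in `[0, 1]` placed in-criteria;
#'   exactly `ceiling(fraction * n_frames)` frames satisfy the criteria.
#' @return List of class `planted_contact`.
#' @export
planted_contact <- function(type = c("point", "pi"), distance = NULL,
                            beta = 170, alpha = 0, theta = 170,
                            fraction = 1.0) {
  type <- match.arg(type)
  if (is.null(distance)) distance <- if (type == "point") 2.95 else 3.40
  stopifnot(fraction >= 0, fraction <= 1, distance > 0)
  structure(list(type = type, distance = distance, beta = beta,
                 alpha = alpha, theta = theta, fraction = fraction),
            class = "planted_contact")
}

#' Specification for a synthetic toy complex
#'
#' Defaults mirror the study conditions the package is exercised under:
#' 1000 frames per trajectory, a dominant point halogen bond at 95.08%
#' occupancy and a ring (pi) halogen bond at 80% occupancy, and key
#' catalytic distances distributed as D_C8-SG ~ N(3.76, 0.21^2) and
#' D_N1-HZ ~ N(2.83, 0.56^2) Angstroms (a productive wild-type-like
#' binding conformation).
#'
#' @param n_frames Number of frames.
#' @param seed Integer seed governing all randomness.
#' @param contacts List of [planted_contact()] objects.
#' @param key_targets Named list of `c(mean, sd)` targets (Angstroms) for
#'   the labels `"D_C8-SG"` and `"D_N1-HZ"`.
#' @param jitter_sigma SD of Gaussian positional jitter applied to
#'   background atoms (never to atoms anchoring a planted geometry),
#'   Angstroms.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_frames = 1000L, seed = 1L,
                           contacts = list(
                             planted_contact("point", fraction = 0.9508),
                             planted_contact("pi", fraction = 0.80)),
                           key_targets = list(
                             "D_C8-SG" = c(mean = 3.76, sd = 0.21),
                             "D_N1-HZ" = c(mean = 2.83, sd = 0.56)),
                           jitter_sigma = 0.05) {
  stopifnot(n_frames >= 1L, jitter_sigma >= 0)
  for (ct in contacts) stopifnot(inherits(ct, "planted_contact"))
  for (lb in names(key_targets)) {
    kt <- key_targets[[lb]]
    if (kt[["mean"]] <= 0)
      stop("specification error: key-distance mean for ", lb, " must be > 0")
    if (kt[["sd"]] < 0)
      stop("specification error: key-distance sd for ", lb, " must be >= 0")
    if (!lb %in% c("D_C8-SG", "D_N1-HZ"))
      stop("specification error: unknown key-distance label '", lb,
           "' (toy topology defines D_C8-SG and D_N1-HZ)")
  }
  structure(list(n_frames = as.integer(n_frames), seed = as.integer(seed),
                 contacts = contacts, key_targets = key_targets,
                 jitter_sigma = jitter_sigma),
            class = "synthetic_spec")
}

# static toy topology; the ligand is a chloro-benzyl-cyanide analogue
# (ring C1-C6, Cl on C1, methylene C7, nitrile C8#N1) so selections like
# "name C8" or "element Cl" look like the real substrates
toy_topology <- function() {
  data.frame(
    serial = 1:20,
    atom_name = c("C1", "C2", "C3", "C4", "C5", "C6", "CL1", "C7", "C8", "N1",
                  "SG", "HZ", "O",
                  "CG", "CD1", "CD2", "CE1", "CE2", "CZ",
                  "N"),
    residue_name = c(rep("LIG", 10), "CYS", "LYS", "GLY", rep("PHE", 6), "ILE"),
    residue_number = c(rep(1L, 10), 169L, 135L, 195L, rep(202L, 6), 201L),
    chain_id = c(rep("L", 10), rep("A", 10)),
    element = c(rep("C", 6), "Cl", "C", "C", "N",
                "S", "H", "O", rep("C", 6), "N"),
    stringsAsFactors = FALSE)
}

hexagon <- function(center, e1, e2, radius = 1.39) {
  ang <- (0:5) * pi / 3
  t(vapply(ang, function(a) center + radius * (cos(a) * e1 + sin(a) * e2),
           numeric(3)))
}

# orthonormal basis perpendicular to unit vector n
perp_basis <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / vnorm(e1)
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# base (frame-independent) ligand coordinates
toy_ligand_coords <- function() {
  ring <- hexagon(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  rbind(ring,
        CL1 = c(3.13, 0, 0),      # on C1, C-Cl 1.74 A along +x
        C7  = c(-2.89, 0, 0),     # para position chain
        C8  = c(-4.35, 0, 0),
        N1  = c(-5.51, 0, 0))
}

# geometry of one planted contact, given the donor (C1 at (1.39,0,0),
# CL1 at (3.13,0,0), C->X axis +x) and whether this frame is in-criteria
contact_positions <- function(contact, in_criteria, criteria) {
  cl <- c(3.13, 0, 0)
  if (contact$type == "point") {
    d <- if (in_criteria) contact$distance
         else criteria_cutoff(criteria, "Cl", "O") + 0.35
    phi <- (180 - contact$beta) * pi / 180
    u <- c(cos(phi), 0, sin(phi))
    list(O = cl + d * u)
  } else {
    d <- if (in_criteria) contact$distance else criteria$pi_d_max + 0.35
    phi <- -(180 - contact$theta) * pi / 180
    u <- c(cos(phi), 0, sin(phi))
    centroid <- cl + d * u
    psi <- phi + contact$alpha * pi / 180
    normal <- c(cos(psi), 0, sin(psi))
    b <- perp_basis(normal)
    list(ring = hexagon(centroid, b$e1, b$e2))
  }
}

validate_contact_feasible <- function(contact, criteria) {
  if (contact$type == "point") {
    cutoff <- criteria_cutoff(criteria, "Cl", "O")
    if (contact$distance >= cutoff - 0.1 || contact$beta <= criteria$beta_min + 5)
      stop("specification error: point contact target (d = ", contact$distance,
           ", beta = ", contact$beta, ") is not decisively inside the criteria")
  } else {
    if (contact$distance >= criteria$pi_d_max - 0.1 ||
        contact$alpha >= criteria$alpha_max - 5 ||
        contact$theta <= criteria$theta_min + 5)
      stop("specification error: pi contact target (d = ", contact$distance,
           ", alpha = ", contact$alpha, ", theta = ", contact$theta,
           ") is not decisively inside the criteria")
  }
  invisible(TRUE)
}

rnorm_trunc <- function(n, mean, sd, lower = 0.5) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower)
  }
  x
}

#' Generate a toy active-site trajectory with planted halogen bonds
#'
#' Builds a multi-frame complex around the fixed toy topology: ligand
#' (LIG 1, chain L; donor pair C1-CL1), a backbone-oxygen acceptor
#' (GLY 195 O), an aromatic ring (PHE 202), catalytic pseudo-atoms
#' (CYS 169 SG, LYS 135 HZ) and a distant distractor (ILE 201 N). For
#' each planted contact exactly `ceiling(fraction * n_frames)` frames
#' (chosen by seeded sampling) satisfy all the criteria of its type;
#' the remaining frames violate the distance criterion by at least
#' 0.3 Angstroms. Catalytic key distances are drawn per frame from the
#' spec's Gaussian targets (truncated at 0.5 Angstroms). Deterministic
#' for a given seed.
#'
#' @param spec A [synthetic_spec()].
#' @param criteria Criteria the contacts are planted against (defaults
#'   to [xbond_criteria()]).
#' @return An [xtraj()]; attribute `planted` records, per contact, the
#'   acceptor residue and the in-criteria frame indices.
#' @export
make_toy_complex <- function(spec = synthetic_spec(),
                             criteria = xbond_criteria()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  for (ct in spec$contacts) validate_contact_feasible(ct, criteria)
  nf <- spec$n_frames
  top <- toy_topology()
  lig <- toy_ligand_coords()

  with_seed(spec$seed, {
    in_frames <- lapply(spec$contacts, function(ct) {
      k <- ceiling(ct$fraction * nf)
      if (k == 0) integer(0) else sort(sample.int(nf, k))
    })
    kt <- spec$key_targets
    d_c8 <- kt[["D_C8-SG"]] %||% c(mean = 3.76, sd = 0.21)
    d_n1 <- kt[["D_N1-HZ"]] %||% c(mean = 2.83, sd = 0.56)
    d1 <- rnorm_trunc(nf, d_c8[["mean"]], d_c8[["sd"]])
    d2 <- rnorm_trunc(nf, d_n1[["mean"]], d_n1[["sd"]])
    # background-atom jitter: ring carbons off the donor axis, the
    # methylene carbon and the distractor nitrogen only
    jit_idx <- c(2, 3, 5, 6, 8, 20)
    jitter <- array(stats::rnorm(length(jit_idx) * 3 * nf, 0, spec$jitter_sigma),
                    dim = c(length(jit_idx), 3, nf))

    coords <- array(NA_real_, dim = c(20, 3, nf))
    point_ct <- which(vapply(spec$contacts, function(ct) ct$type == "point", TRUE))
    pi_ct <- which(vapply(spec$contacts, function(ct) ct$type == "pi", TRUE))
    # default (far away) placements when a contact type is absent
    far_O <- c(9, 9, 9)
    far_ring <- hexagon(c(-9, 9, 9), c(1, 0, 0), c(0, 1, 0))
    for (f in seq_len(nf)) {
      xyz <- matrix(NA_real_, 20, 3)
      xyz[1:10, ] <- lig
      xyz[11, ] <- lig[9, ] + d1[f] * c(0, 1, 0)   # SG above C8
      xyz[12, ] <- lig[10, ] + d2[f] * c(0, -1, 0) # HZ below N1
      xyz[13, ] <- far_O
      xyz[14:19, ] <- far_ring
      if (length(point_ct)) {
        ct <- spec$contacts[[point_ct[1]]]
        xyz[13, ] <- contact_positions(ct, f %in% in_frames[[point_ct[1]]],
                                       criteria)$O
      }
      if (length(pi_ct)) {
        ct <- spec$contacts[[pi_ct[1]]]
        xyz[14:19, ] <- contact_positions(ct, f %in% in_frames[[pi_ct[1]]],
                                          criteria)$ring
      }
      xyz[20, ] <- c(8, 9, 3)
      xyz[jit_idx, ] <- xyz[jit_idx, ] + jitter[, , f]
      coords[, , f] <- xyz
    }
    out <- xtraj(top, coords)
    attr(out, "planted") <- mapply(function(ct, fr) {
      list(type = ct$type,
           residue = if (ct$type == "point") "GLY195.A" else "PHE202.A",
           fraction = ct$fraction, in_frames = fr)
    }, spec$contacts, in_frames, SIMPLIFY = FALSE)
    out
  })
}

#' Generate frames with Gaussian-distributed key distances
#'
#' A thin specialization of [make_toy_complex()]: no halogen-bond
#' contacts are planted (acceptors sit far from the ligand) and the
#' catalytic key distances D_C8-SG and D_N1-HZ are drawn per frame from
#' the given Gaussian targets, truncated at 0.5 Angstroms.
#'
#' @param label_targets Named list of `c(mean, sd)` pairs (Angstroms)
#'   for `"D_C8-SG"` and/or `"D_N1-HZ"`.
#' @param n_frames Number of frames (default 1000).
#' @param seed Integer seed.
#' @return An [xtraj()].
#' @export
#' @examples
#' traj <- make_key_distance_frames(list("D_C8-SG" = c(mean = 3.76, sd = 0.21)),
#'                                  n_frames = 100, seed = 7)
make_key_distance_frames <- function(label_targets, n_frames = 1000L, seed = 1L) {
  spec <- synthetic_spec(n_frames = n_frames, seed = seed,
                         contacts = list(), key_targets = label_targets)
  make_toy_complex(spec)
}

# the two canonical key-distance specs on the toy topology
toy_distance_specs <- function() {
  list(distance_spec("D_C8-SG", "resid 1 and name C8", "resid 169 and name SG"),
       distance_spec("D_N1-HZ", "resid 1 and name N1", "resid 135 and name HZ"))
}

#' Generate a wild-type / mutant screening scenario with known verdict
#'
#' Draws wild-type key-distance means from a non-productive range
#' (D_C8-SG in 5.5-8, D_N1-HZ in 7-10 Angstroms), then plants mutant
#' means either strictly below both (expected `"pass"`) or at or above
#' at least one (expected `"fail"`), with margins of at least 0.5
#' Angstroms so sampling noise cannot flip the verdict. Frame-level SDs
#' are 0.21 and 0.56 Angstroms. Returns both trajectories and the
#' planted verdict for end-to-end validation of the screening pipeline.
#'
#' @param seed Integer seed.
#' @param n_frames Frames per trajectory (default 1000).
#' @return List: `wt` and `mutant` ([xtraj()]s), `expected_verdict`
#'   (`"pass"`/`"fail"`), `specs` (the two [distance_spec()]s), and the
#'   planted means.
#' @export
wt_vs_mutant_scenario <- function(seed = 1L, n_frames = 1000L) {
  params <- with_seed(seed, {
    mu_wt <- c(stats::runif(1, 5.5, 8), stats::runif(1, 7, 10))
    expect_pass <- stats::runif(1) < 0.5
    if (expect_pass) {
      mu_mut <- mu_wt - stats::runif(2, 1.5, 3)
    } else {
      mode <- sample.int(3, 1)  # which distance(s) violate the rule
      viol <- switch(mode, c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))
      mu_mut <- ifelse(viol, mu_wt + stats::runif(2, 0.5, 2),
                       mu_wt - stats::runif(2, 0.5, 2))
    }
    list(mu_wt = mu_wt, mu_mut = mu_mut, expect_pass = expect_pass)
  })
  sds <- c(0.21, 0.56)
  tgt <- function(mu) list("D_C8-SG" = c(mean = mu[1], sd = sds[1]),
                           "D_N1-HZ" = c(mean = mu[2], sd = sds[2]))
  list(wt = make_key_distance_frames(tgt(params$mu_wt), n_frames,
                                     seed = seed * 2L + 1L),
       mutant = make_key_distance_frames(tgt(params$mu_mut), n_frames,
                                         seed = seed * 2L + 2L),
       expected_verdict = if (params$expect_pass) "pass" else "fail",
       specs = toy_distance_specs(),
       wt_means = params$mu_wt, mutant_means = params$mu_mut)
}
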