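# Angles, ring planes and the single-frame halogen-bond checks.

test_that("vertex angles match closed forms and reject degenerate arms", {
  expect_equal(vec_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(vec_angle(c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0)), 180)
  expect_equal(vec_angle(c(1, 0, 0), c(0, 0, 0), c(1, 1, 0)), 45)
  expect_error(vec_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "degenerate")
})

test_that("pair cutoffs reproduce vdW sums and are symmetric", {
  expect_identical(cutoff_for_pair("Cl", "O"), 3.27)
  expect_identical(cutoff_for_pair("Cl", "N"), 3.30)
  expect_identical(cutoff_for_pair("Cl", "S"), 3.55)
  els <- names(bondi_radii())
  for (x in els) for (y in els)
    expect_identical(cutoff_for_pair(x, y), cutoff_for_pair(y, x))
})

test_that("ring planes recover centroid and normal of a planar hexagon", {
  ang <- (0:5) * pi / 3
  hex <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  pl <- ring_plane(hex)
  expect_equal(pl$centroid, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)
  expect_equal(pl$rmsd, 0, tolerance = 1e-12)
})

test_that("least-squares plane of a puckered ring matches the grid-search oracle", {
  ang <- (0:5) * pi / 3
  hex <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  hex[1, 3] <- hex[1, 3] + 0.1
  pl <- ring_plane(hex)
  ang_to_z <- acos(abs(pl$normal[3])) * 180 / pi
  expect_lt(ang_to_z, 3)
  oracle <- oracle_plane_normal(hex)
  ang_between <- acos(min(1, abs(sum(pl$normal * oracle)))) * 180 / pi
  expect_lt(ang_between, 1.5)
})

test_that("degenerate rings are rejected", {
  expect_error(ring_plane(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))), "collinear")
  expect_error(ring_plane(rbind(c(0, 0, 0), c(1, 0, 0))), "at least 3")
})

test_that("point checks enforce strict distance and angle criteria", {
  crit <- xbond_criteria()
  hit <- point_xbond_check(c(0, 0, 0), c(1.70, 0, 0), c(4.70, 0, 0), "Cl", "O", crit)
  expect_equal(hit$distance, 3.0)
  expect_equal(hit$beta, 180)
  # angle fails
  expect_null(point_xbond_check(c(0, 0, 0), c(1.70, 0, 0), c(1.70, 3.0, 0),
                                "Cl", "O", crit))
  # exact boundary (d = 3.27) is not a bond (strict <)
  expect_null(point_xbond_check(c(-1.70, 0, 0), c(0, 0, 0),
                                c(cutoff_for_pair("Cl", "O"), 0, 0),
                                "Cl", "O", crit))
  # boundary beta is not a bond either
  y <- c(1.70, 0, 0) + 3.0 * c(cos(40 * pi / 180), sin(40 * pi / 180), 0)
  expect_null(point_xbond_check(c(0, 0, 0), c(1.70, 0, 0), y, "Cl", "O", crit))
})

test_that("pi checks enforce strict d, alpha and theta criteria", {
  crit <- xbond_criteria()
  ang <- (0:5) * pi / 3
  hex <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  ring <- ring_plane(hex)
  hit <- pi_xbond_check(c(0, 0, 5.2), c(0, 0, 3.5), ring, crit)
  expect_equal(hit$distance, 3.5)
  expect_equal(hit$alpha, 0, tolerance = 1e-9)
  expect_equal(hit$theta, 180)
  # in-plane approach fails alpha
  expect_null(pi_xbond_check(c(6.7, 0, 0), c(5.0, 0, 0), ring, crit))
  # exact boundary distance is not a bond
  expect_null(pi_xbond_check(c(0, 0, 6.1), c(0, 0, 4.2), ring, crit))
})

test_that("alpha is invariant under ring-normal sign flip", {
  set.seed(42)
  for (i in 1:10) {
    ang <- (0:5) * pi / 3
    R <- random_rotation()
    hex <- t(apply(cbind(1.39 * cos(ang), 1.39 * sin(ang), 0), 1,
                   function(p) as.vector(R %*% p)))
    ring <- ring_plane(hex)
    flipped <- ring; flipped$normal <- -ring$normal
    x <- rnorm(3); x <- 3.0 * x / sqrt(sum(x^2))
    cpos <- x * 1.5
    a <- pi_xbond_check(cpos, x, ring, xbond_criteria(alpha_max = 90, theta_min = 1))
    b <- pi_xbond_check(cpos, x, flipped, xbond_criteria(alpha_max = 90, theta_min = 1))
    if (!is.null(a)) {
      expect_equal(a$alpha, b$alpha, tolerance = 1e-9)
      expect_equal(a$theta, b$theta, tolerance = 1e-9)
    } else expect_null(b)
  }
})

test_that("planted frame detections are found, and only those", {
  tr <- make_toy_complex(synthetic_spec(
    n_frames = 1, seed = 9,
    contacts = list(planted_contact("point", fraction = 1))))
  obs <- detect_frame_xbonds(tr, 1, donors = find_donors(tr, "resname LIG"))
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$bond_type, "point")
  expect_equal(obs$acceptor_residue, "GLY195.A")

  tr2 <- make_toy_complex(synthetic_spec(
    n_frames = 1, seed = 9,
    contacts = list(planted_contact("point", fraction = 1),
                    planted_contact("pi", fraction = 1))))
  obs2 <- detect_frame_xbonds(tr2, 1, donors = find_donors(tr2, "resname LIG"))
  expect_equal(nrow(obs2), 2L)
  expect_setequal(obs2$bond_type, c("point", "pi"))
})

test_that("detector matches the exhaustive brute-force oracle on random frames", {
  crit <- xbond_criteria()
  for (seed in 1:8) {
    tr <- random_contact_frame(seed)
    donors <- list(c(1L, 2L))
    obs <- suppressWarnings(detect_frame_xbonds(tr, 1, donors, crit))
    expect_identical(detector_keys(obs, tr),
                     oracle_detect_keys(tr, 1, donors, crit),
                     info = paste("seed", seed))
  }
})

test_that("recorded geometry always satisfies the strict criteria", {
  crit <- xbond_criteria()
  for (seed in 11:16) {
    tr <- random_contact_frame(seed)
    obs <- suppressWarnings(detect_frame_xbonds(tr, 1, list(c(1L, 2L)), crit))
    if (!nrow(obs)) next
    pt <- obs[obs$bond_type == "point", ]
    if (nrow(pt)) expect_true(all(pt$beta > crit$beta_min))
    pi_ <- obs[obs$bond_type == "pi", ]
    if (nrow(pi_)) {
      expect_true(all(pi_$distance < crit$pi_d_max))
      expect_true(all(pi_$alpha < crit$alpha_max))
      expect_true(all(pi_$theta > crit$theta_min))
    }
  }
})

test_that("detections are invariant under rigid motion of the frame", {
  set.seed(7)
  tr <- random_contact_frame(3)
  obs0 <- suppressWarnings(detect_frame_xbonds(tr, 1, list(c(1L, 2L))))
  for (i in 1:5) {
    trR <- rigid_transform(tr)
    obsR <- suppressWarnings(detect_frame_xbonds(trR, 1, list(c(1L, 2L))))
    expect_identical(detector_keys(obsR, trR), detector_keys(obs0, tr))
    expect_equal(obsR$distance, obs0$distance, tolerance = 1e-6)
    expect_equal(obsR$beta, obs0$beta, tolerance = 1e-6)
    expect_equal(obsR$alpha, obs0$alpha, tolerance = 1e-6)
    expect_equal(obsR$theta, obs0$theta, tolerance = 1e-6)
  }
})

test_that("a stretched donor pair warns but is still processed", {
  tr <- make_toy_complex(synthetic_spec(n_frames = 1, seed = 1))
  co <- tr$coords
  co[7, 1, 1] <- co[7, 1, 1] + 1.0  # pull the halogen off its carbon
  tr2 <- xtraj(tr$topology, co)
  expect_warning(detect_frame_xbonds(tr2, 1, list(c(1L, 7L))), "2.1")
})

test_that("criteria config files override thresholds and pair cutoffs", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# tightened thresholds", "beta_min = 150", "pi_d_max = 4.0",
               "Cl-O = 3.10"), f)
  crit <- read_criteria_config(f)
  expect_equal(crit$beta_min, 150)
  expect_equal(crit$pi_d_max, 4.0)
  expect_equal(xbondr:::criteria_cutoff(crit, "Cl", "O"), 3.10)
  expect_equal(xbondr:::criteria_cutoff(crit, "O", "Cl"), 3.10)
  expect_equal(xbondr:::criteria_cutoff(crit, "Cl", "N"), 3.30)
})
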