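# Distance time series, mean +/- SD summaries, per-residue occupancy
# and the combined analysis report.

test_that("distance series are per-frame Euclidean distances in order", {
  top <- data.frame(serial = 1:2, atom_name = c("C8", "SG"),
                    residue_name = c("LIG", "CYS"),
                    residue_number = c(1L, 169L), chain_id = "A",
                    element = c("C", "S"), stringsAsFactors = FALSE)
  coords <- array(0, dim = c(2, 3, 2))
  coords[2, , 1] <- c(3, 0, 0)
  coords[2, , 2] <- c(0, 4, 0)
  tr <- xtraj(top, coords)
  s <- distance_series(tr, distance_spec("d", "name C8", "name SG"))
  expect_equal(s$values, c(3, 4))
})

test_that("ambiguous selections raise a specification error naming the selection", {
  tr <- make_toy_complex(synthetic_spec(n_frames = 2, seed = 1))
  expect_error(distance_series(tr, distance_spec("d", "element C", "name SG")),
               "exactly 1 atom")
  expect_error(distance_series(tr, distance_spec("d", "element C", "name SG")),
               "element C")
})

test_that("distance series are invariant under rigid motion", {
  tr <- make_toy_complex(synthetic_spec(n_frames = 20, seed = 4))
  sp <- distance_spec("D_C8-SG", "resid 1 and name C8", "resid 169 and name SG")
  s0 <- distance_series(tr, sp)$values
  set.seed(99)
  for (i in 1:3)
    expect_equal(distance_series(rigid_transform(tr), sp)$values, s0,
                 tolerance = 1e-6)
})

test_that("summaries use the arithmetic mean and n-1 standard deviation", {
  expect_equal(summarize_series(c(3, 3, 3))$mean, 3)
  expect_equal(summarize_series(c(3, 3, 3))$sd, 0)
  s <- summarize_series(c(2, 4))
  expect_equal(s$mean, 3)
  expect_equal(s$sd, sqrt(2), tolerance = 1e-4)
  expect_warning(s1 <- summarize_series(5), "sd reported as 0")
  expect_equal(s1$sd, 0)
  expect_error(summarize_series(numeric(0)), "empty")
})

test_that("seeded Gaussian draws recover the target mean within sampling bounds", {
  set.seed(2024)
  x <- rnorm(1000, 3.76, 0.21)
  s <- summarize_series(x, label = "D_C8-SG")
  expect_lt(abs(s$mean - 3.76), 3 * 0.21 / sqrt(1000))
})

test_that("duplicating a series keeps the mean and rescales the n-1 SD analytically", {
  set.seed(5)
  x <- rnorm(40, 6, 0.8)
  s1 <- summarize_series(x)
  s2 <- summarize_series(c(x, x))
  expect_equal(s2$mean, s1$mean)
  n <- length(x)
  expect_equal(s2$sd, sqrt(s1$sd^2 * (n - 1) * 2 / (2 * n - 1)), tolerance = 1e-12)
})

test_that("occupancy equals the planted in-criteria frame fraction", {
  mk <- function(frac) make_toy_complex(synthetic_spec(
    n_frames = 10, seed = 21,
    contacts = list(planted_contact("point", fraction = frac))))
  occ1 <- occupancy_profile(mk(1.0), ligand = "resname LIG")
  expect_equal(occ1$fraction[occ1$residue == "GLY195.A" & occ1$type == "all"], 1.0)
  occ0 <- occupancy_profile(mk(0.0), ligand = "resname LIG")
  expect_false("GLY195.A" %in% occ0$residue)
  occ8 <- occupancy_profile(mk(0.8), ligand = "resname LIG")
  expect_equal(occ8$fraction[occ8$residue == "GLY195.A" & occ8$type == "all"], 0.8)
})

test_that("occupancy agrees with the per-frame brute-force oracle", {
  tr <- make_toy_complex(synthetic_spec(
    n_frames = 10, seed = 31,
    contacts = list(planted_contact("point", fraction = 0.8))))
  donors <- find_donors(tr, "resname LIG")
  crit <- xbond_criteria()
  hit_frames <- vapply(1:10, function(f)
    any(grepl("^point", oracle_detect_keys(tr, f, donors, crit))), TRUE)
  occ <- occupancy_profile(tr, donors = donors, criteria = crit)
  expect_equal(occ$fraction[occ$residue == "GLY195.A" & occ$type == "all"],
               mean(hit_frames))
})

test_that("occupancy counts a residue once per frame even with simultaneous bonds", {
  # both a point bond (GLY O) and a pi bond (PHE ring) every frame:
  # pooled occupancy for each residue is 1, and the pooled table never
  # exceeds 1 for any residue
  tr <- make_toy_complex(synthetic_spec(
    n_frames = 5, seed = 8,
    contacts = list(planted_contact("point", fraction = 1),
                    planted_contact("pi", fraction = 1))))
  occ <- occupancy_profile(tr, ligand = "resname LIG")
  expect_true(all(occ$fraction <= 1))
  expect_setequal(occ$residue[occ$type == "all"], c("GLY195.A", "PHE202.A"))
  expect_equal(occ$fraction[occ$type == "all"], c(1, 1))
})

test_that("occupancy is monotone non-increasing as criteria tighten", {
  tr <- make_toy_complex(synthetic_spec(
    n_frames = 12, seed = 13,
    contacts = list(planted_contact("point", distance = 2.9, beta = 160,
                                    fraction = 0.75))))
  donors <- find_donors(tr, "resname LIG")
  frac_at <- function(crit) {
    occ <- occupancy_profile(tr, donors = donors, criteria = crit)
    f <- occ$fraction[occ$residue == "GLY195.A" & occ$type == "all"]
    if (length(f)) f else 0
  }
  # sweep the pair cutoff down and beta_min up: occupancy can only drop
  cuts <- c(3.27, 3.05, 2.95, 2.85)
  occs <- vapply(cuts, function(cc)
    frac_at(xbond_criteria(point_cutoffs = list("Cl-O" = cc))), 0)
  expect_true(all(diff(occs) <= 0))
  betas <- c(140, 150, 158, 165)
  occs_b <- vapply(betas, function(b) frac_at(xbond_criteria(beta_min = b)), 0)
  expect_true(all(diff(occs_b) <= 0))
})

test_that("statistics are invariant under frame reordering", {
  tr <- make_toy_complex(synthetic_spec(
    n_frames = 15, seed = 17,
    contacts = list(planted_contact("point", fraction = 0.6))))
  set.seed(1)
  perm <- sample(15)
  tr_p <- xtraj(tr$topology, tr$coords[, , perm])
  sp <- distance_spec("D_C8-SG", "resid 1 and name C8", "resid 169 and name SG")
  s <- summarize_series(distance_series(tr, sp))
  s_p <- summarize_series(distance_series(tr_p, sp))
  expect_equal(s_p$mean, s$mean)
  expect_equal(s_p$sd, s$sd)
  o <- occupancy_profile(tr, ligand = "resname LIG")
  o_p <- occupancy_profile(tr_p, ligand = "resname LIG")
  expect_equal(o_p$fraction, o$fraction)
})

test_that("the analysis report carries every summary and serializes deterministically", {
  tr <- make_toy_complex(synthetic_spec(
    n_frames = 8, seed = 23,
    key_targets = list("D_C8-SG" = c(mean = 3.5, sd = 0),
                       "D_N1-HZ" = c(mean = 2.9, sd = 0))))
  an <- xbond_analysis(tr, xbondr:::toy_distance_specs(),
                       ligand = "resname LIG", label = "toy")
  expect_length(an$summaries, 2L)
  expect_equal(an$summaries[["D_C8-SG"]]$mean, 3.5, tolerance = 1e-12)
  expect_equal(an$summaries[["D_N1-HZ"]]$mean, 2.9, tolerance = 1e-12)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(an, d1)
  write_report(an, d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  occ_csv <- utils::read.csv(file.path(d1, "occupancy.csv"))
  expect_true(all(c("residue", "type", "fraction") %in% names(occ_csv)))
  expect_identical(
    sum(utils::read.csv(file.path(d1, "distances.csv"))$label == "D_C8-SG"), 8L)
})
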