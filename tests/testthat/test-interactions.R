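# interactions: contacts, hydrogen bonds, secondary structure, SASA, patches.

test_that("contact counts honour the 4 A threshold and the O(n^2) oracle", {
  top <- atoms_topology(2)
  mk <- function(d) {
    coords <- array(0, dim = c(1, 2, 3))
    coords[1, 2, 1] <- d
    traj_from(top, coords)
  }
  expect_equal(count_contacts(mk(3.9), 1, 2), 1L)
  expect_equal(count_contacts(mk(4.1), 1, 2), 0L)

  set.seed(23)
  top40 <- atoms_topology(40)
  coords <- array(runif(2 * 40 * 3, 0, 12), dim = c(2, 40, 3))
  tr <- traj_from(top40, coords)
  ga <- 1:20; gb <- 21:40
  got <- count_contacts(tr, ga, gb, cutoff = 4)
  want <- vapply(1:2, function(f) {
    cnt <- 0L
    for (i in ga) for (j in gb) {
      if (sqrt(sum((coords[f, i, ] - coords[f, j, ])^2)) < 4) cnt <- cnt + 1L
    }
    cnt
  }, integer(1))
  expect_identical(got, want)
  # symmetric in group order
  expect_identical(count_contacts(tr, gb, ga, cutoff = 4), got)
  expect_error(count_contacts(tr, integer(0), gb), "empty")
  expect_error(count_contacts(tr, 1:5, 3:8), "disjoint")
})

test_that("hydrogen bonds follow the geometric rule and frequency cutoff", {
  fx <- make_structure_fixtures()
  good <- fx$triad(1.8, 180)
  tr <- fixture_traj(good, n_frames = 3)
  hb <- hydrogen_bonds(tr)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$frequency, 1)
  expect_match(hb$donor_id, "ALA1/N")

  # bent triad never detected
  expect_equal(nrow(hydrogen_bonds(fixture_traj(fx$triad(1.8, 90)))), 0)
  # distant triad never detected
  expect_equal(nrow(hydrogen_bonds(fixture_traj(fx$triad(2.8, 180)))), 0)

  # 1-of-200 frames = 0.5% occupancy: below the 1% frequency cutoff
  xyz <- as.matrix(good[, c("x", "y", "z")])
  coords <- array(NA_real_, dim = c(200, 3, 3))
  for (f in 1:200) {
    coords[f, , ] <- xyz
    if (f > 1) coords[f, 3, 1] <- coords[f, 3, 1] + 50  # acceptor far away
  }
  tr200 <- traj_from(good, coords)
  expect_equal(nrow(hydrogen_bonds(tr200, freq_cutoff = 0.01)), 0)
  kept <- hydrogen_bonds(tr200, freq_cutoff = 0.004)
  expect_equal(kept$frequency, 1 / 200)

  # frequency invariant under frame reordering
  coords_rev <- coords[200:1, , , drop = FALSE]
  tr_rev <- traj_from(good, coords_rev)
  expect_equal(hydrogen_bonds(tr_rev, freq_cutoff = 0.004)$frequency, 1 / 200)

  no_h <- atoms_topology(3)
  expect_error(hydrogen_bonds(fixture_traj(no_h)), "no hydrogens")
})

test_that("Kabsch-Sander energies on the ideal helix support the H assignment", {
  fx <- make_structure_fixtures()
  hel <- fx$helix
  at <- function(nm, i) unlist(hel[hel$name == nm & hel$resid == i,
                                   c("x", "y", "z")])
  # manual i -> i+4 bond energy for an interior turn
  for (i in 3:8) {
    r_on <- sqrt(sum((at("O", i) - at("N", i + 4))^2))
    r_ch <- sqrt(sum((at("C", i) - at("H", i + 4))^2))
    r_oh <- sqrt(sum((at("O", i) - at("H", i + 4))^2))
    r_cn <- sqrt(sum((at("C", i) - at("N", i + 4))^2))
    e <- 0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
    expect_lt(e, -0.5)
  }
  ss <- secondary_structure(fixture_traj(hel))
  codes <- ss$codes[, 1]
  expect_true(all(codes[3:12] == "H"))
  expect_equal(unname(ss$frequency[5, "H"]), 100)
  expect_equal(unname(ss$categories[5, "helix"]), 100)
})

test_that("antiparallel ladder is assigned E and short chains stay coil", {
  fx <- make_structure_fixtures()
  ss <- secondary_structure(fixture_traj(fx$sheet))
  res <- ss$residues
  interior <- which(res$resid %in% 2:4)
  expect_true(all(ss$codes[interior, 1] == "E"))

  duo <- build_dipeptide()
  ss2 <- secondary_structure(fixture_traj(duo))
  expect_true(all(ss2$codes %in% c("-", "S", "T")))
})

test_that("SASA matches analytic sphere results", {
  fx <- make_structure_fixtures()
  s1 <- sasa(fixture_traj(fx$single_atom), radii = c(C = 1.5))
  expect_equal(s1$atom[1, 1], 4 * pi * (1.5 + 1.4)^2, tolerance = 0.01)

  # buried atom in a tight cage
  sc <- sasa(fixture_traj(fx$caged_atom))
  expect_equal(sc$atom[1, 1], 0)

  # two-sphere closed form: each sphere loses a cap of height r - d/2
  r <- 1.7 + 1.4
  for (d in c(2.0, 3.5, 5.0)) {
    s2 <- sasa(fixture_traj(fx$two_spheres(d)))
    analytic <- 4 * pi * r^2 - 2 * pi * r * (r - d / 2)
    expect_equal(s2$atom[1, 1], analytic, tolerance = analytic * 0.015)
    expect_equal(s2$atom[2, 1], analytic, tolerance = analytic * 0.015)
  }

  # monotonicity: adding atoms can only reduce per-atom SASA
  iso <- sasa(fixture_traj(fx$single_atom))
  s2 <- sasa(fixture_traj(fx$two_spheres(2.5)))
  expect_lt(s2$atom[1, 1], iso$atom[1, 1])

  odd <- atoms_topology(1)
  odd$element <- "ZZ"
  expect_warning(sasa(fixture_traj(odd)), "unknown element")
})

test_that("surface patches connect exposed same-class residues", {
  # two exposed LEU pseudo-residues 6 A apart, one ARG far away
  top <- atoms_topology(3)
  top$resname <- c("LEU", "LEU", "ARG")
  top$resid <- 1:3
  coords <- array(0, dim = c(1, 3, 3))
  coords[1, 2, 1] <- 6
  coords[1, 3, 1] <- 40
  tr <- traj_from(top, coords)
  sa <- sasa(tr)
  ps <- surface_patches(tr, sa, adjacency_cutoff = 8)
  hydro <- ps$patches[ps$patches$type == "hydrophobic", ]
  expect_equal(nrow(hydro), 1)
  expect_equal(hydro$n_residues, 2)
  expect_equal(hydro$area, sum(sa$residue$frame_1[1:2]))
  expect_equal(ps$patches$type[ps$patches$n_residues == 1], "positive")

  # with a tighter cutoff the two LEU split into two patches
  ps2 <- surface_patches(tr, sa, adjacency_cutoff = 5)
  expect_equal(sum(ps2$patches$type == "hydrophobic"), 2)
  # total per type conserved regardless of connectivity
  expect_equal(sum(ps2$patches$area[ps2$patches$type == "hydrophobic"]),
               hydro$area)

  # buried residues yield no patches
  fx <- make_structure_fixtures()
  cage <- fx$caged_atom
  cage$resname <- "LEU"
  trc <- fixture_traj(cage)
  sac <- sasa(trc)
  # bury everything by claiming a huge reference area via threshold 1.0
  psc <- surface_patches(trc, sac, exposure_threshold = 1.0)
  expect_equal(nrow(psc$patches), 0)
})
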