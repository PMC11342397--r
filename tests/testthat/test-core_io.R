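# core_io: trajectory/annotation/boost loaders and the data model.

test_that("load_trajectory applies stride and selection correctly", {
  toy <- const_toy(70, 70, n = 10)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  dcd <- withr::local_tempfile(fileext = ".dcd")
  write_pdb(toy$topology, pdb)
  write_dcd(toy$traj$coords, dcd)

  tr <- load_trajectory(pdb, dcd, stride = 2)
  expect_equal(n_frames(tr), 5)
  expect_equal(tr$frame_index, c(0L, 2L, 4L, 6L, 8L))

  tr1 <- load_trajectory(pdb, dcd, stride = 1)
  expect_equal(tr1$frame_index, 0:9)
  # DCD stores float32: round trip to that precision
  expect_lt(max(abs(tr1$coords - toy$traj$coords)), 1e-4)

  # Calpha selection: one atom per protein residue
  top <- read_pdb(pdb)
  ca <- select_atoms(top, name = "CA")
  n_protein_res <- length(unique(paste(top$chain, top$resid)[top$chain %in% c("A", "B", "C", "D")]))
  trc <- load_trajectory(pdb, dcd, selection = ca)
  expect_equal(dim(trc$coords)[2], n_protein_res)

  expect_error(load_trajectory(pdb, "missing.dcd"), "not found")
  expect_error(load_trajectory(pdb, dcd, selection = integer(0)), "empty")
  expect_error(load_trajectory(pdb, sub("dcd$", "xtc", dcd)), "not supported")
})

test_that("multi-model PDB frames round-trip through write_pdb", {
  toy <- const_toy(60, 80, n = 4)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(toy$topology, pdb, coords = toy$traj$coords)
  tr <- load_trajectory(pdb)
  expect_equal(n_frames(tr), 4)
  expect_lt(max(abs(tr$coords - toy$traj$coords)), 1e-3)  # %8.3f columns
})

test_that("annotation config round-trips and validates", {
  toy <- const_toy(70, 70)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_annotation(toy$system, p1)
  s2 <- load_annotation(p1)
  write_annotation(s2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(s2$chain_map, toy$system$chain_map)
  expect_equal(nrow(s2$residue_sets$hinge), nrow(toy$system$residue_sets$hinge))

  # missing chain label is named in the error
  cm <- toy$system$chain_map
  expect_error(annotated_system(cm[c("LC1", "LC2", "HC1")],
                                toy$system$domain_ranges), "HC2")
  # overlapping intervals rejected
  dr <- toy$system$domain_ranges
  dr$end[dr$label == "HC1" & dr$domain == "VH"] <- 1000L
  expect_error(annotated_system(cm, dr), "overlap")
})

test_that("anchors resolve to exactly one atom", {
  toy <- const_toy(70, 70)
  expect_length(resolve_anchor(toy$system, toy$traj$atoms, "cys228_sg"), 1)
  bad <- toy$system
  bad$anchors$nowhere <- list(label = "HC1", resid = 9999L, atom = "CA")
  expect_error(resolve_anchor(bad, toy$traj$atoms, "nowhere"), "resolves to 0")
})

test_that("boost logs parse in both dialects and align strictly", {
  p <- withr::local_tempfile()
  writeLines(sprintf("%d 0", 0:4), p)
  b <- load_boost_log(p)
  expect_equal(b$delta_v, rep(0, 5))

  # AMBER-style: dV is the sum of potential and dihedral boosts
  pa <- withr::local_tempfile()
  writeLines(c("# header", paste(1:3, 500, -3e3, 4e2, 1, 1, 2.0, 3.0)), pa)
  ba <- load_boost_log(pa, dialect = "amber-amd-log")
  expect_equal(ba$delta_v, rep(5, 3))

  # serialization round trip
  set.seed(4)
  b0 <- boost_series(runif(50, 0, 8))
  pr <- withr::local_tempfile()
  write_boost_table(b0, pr)
  br <- load_boost_log(pr)
  expect_equal(br$delta_v, b0$delta_v, tolerance = 1e-9)

  pn <- withr::local_tempfile()
  writeLines(c("0 1.0", "1 abc"), pn)
  expect_error(load_boost_log(pn), "non-numeric")

  toy <- const_toy(70, 70, n = 3)
  expect_error(check_alignment(b, toy$traj), "5 frames but trajectory has 3")
  expect_error(boost_series(c(1, -2)), ">= 0")
})

test_that("trajectory slice invariants hold", {
  toy <- const_toy(70, 70, n = 4)
  expect_error(trajectory_slice(toy$traj$coords, toy$traj$atoms,
                                frame_index = c(3, 2, 1, 0)), "increasing")
  expect_error(trajectory_slice(toy$traj$coords[, 1:5, , drop = FALSE],
                                toy$traj$atoms), "atoms")
  sub <- subset_frames(toy$traj, c(2, 4))
  expect_equal(sub$frame_index, c(1L, 3L))
})
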