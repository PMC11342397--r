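# geometry: Fc frame, spherical angles, shape rule, delta-phi, distances.

test_that("build_fc_frame produces the constructed orthogonal layout", {
  toy <- const_toy(70, 70)
  fr <- build_fc_frame(frame_coords(toy$traj, 1), toy$system, toy$traj$atoms)
  # layout built with hinge at origin, Fc below, CH2 split along x
  expect_equal(fr$origin, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(fr$z, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fr$x, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(fr$y, c(0, 1, 0), tolerance = 1e-9)
})

test_that("frame axes stay orthonormal and right-handed on random conformations", {
  set.seed(11)
  toy <- const_toy(70, 70)
  xyz0 <- frame_coords(toy$traj, 1)
  for (k in 1:100) {
    r <- random_rotation()
    xyz <- sweep(xyz0 %*% t(r), 2, rnorm(3, 0, 20), `+`)
    fr <- build_fc_frame(xyz, toy$system, toy$traj$atoms)
    expect_lt(abs(sum(fr$x * fr$z)), 1e-10)
    expect_lt(abs(sum(fr$y * fr$z)), 1e-10)
    expect_lt(abs(sum(fr$x * fr$y)), 1e-10)
    expect_equal(det(cbind(fr$x, fr$y, fr$z)), 1, tolerance = 1e-10)
    # equivariance: axes rotate with the system
    expect_equal(fr$z, as.vector(r %*% c(0, 0, 1)), tolerance = 1e-9)
  }
})

test_that("spherical angles handle poles and the equator by convention", {
  toy <- const_toy(0.000000001, 90, phi2 = 0)
  ang <- fab_spherical_angles(toy$traj, toy$system)
  expect_equal(ang$theta1[1], 0, tolerance = 1e-6)
  expect_equal(ang$phi1[1], 0)          # pole convention
  expect_equal(ang$theta2[1], 90, tolerance = 1e-6)
  expect_equal(ang$phi2[1], 0, tolerance = 1e-6)
})

test_that("shape classifier follows the 90-degree rule", {
  expect_equal(classify_shape(70, 70), "Y")
  expect_equal(classify_shape(95, 70), "T")
  expect_equal(classify_shape(90, 10), "T")
  expect_equal(classify_shape(c(89.999, 90), c(10, 10)), c("Y", "T"))
  expect_error(classify_shape(200, 10), "0, 180")
})

test_that("delta_phi unwraps continuous rotation across the seam", {
  expect_equal(delta_phi(rep(25, 10)), rep(0, 10))
  expect_equal(delta_phi(c(10, -60))[2], -70)
  # continuous +300 degree rotation, stored wrapped to (-180, 180]
  true_phi <- seq(0, 300, by = 10)
  wrapped <- ((true_phi + 180) %% 360) - 180
  d <- delta_phi(wrapped, unwrap = TRUE)
  expect_equal(d[length(d)], 300, tolerance = 1e-9)
  expect_equal(d, true_phi - true_phi[1], tolerance = 1e-9)
  # raw mode maps to (-180, 180]
  draw <- delta_phi(wrapped, unwrap = FALSE)
  expect_true(all(draw > -180 & draw <= 180))
  expect_error(delta_phi(numeric(0)), "empty")
})

test_that("inter-Fab angle matches an arccos oracle on random triples", {
  set.seed(21)
  for (k in 1:1000) {
    a <- rnorm(3); v <- rnorm(3); b <- rnorm(3)
    u <- a - v; w <- b - v
    expected <- acos(max(-1, min(1, sum(u * w) / sqrt(sum(u^2) * sum(w^2))))) * 180 / pi
    expect_equal(angle_at_vertex(a, v, b), expected, tolerance = 1e-9)
  }
  expect_equal(angle_at_vertex(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)), 180)
  expect_equal(angle_at_vertex(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_error(angle_at_vertex(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "coincident")
})

test_that("CH2 and glycan distances match brute-force geometry", {
  toy <- const_toy(70, 70)
  # construction: anchor residues mirrored at x = +-5
  expect_equal(ch2_distance(toy$traj, toy$system), rep(10, 5))
  expect_equal(ch2_distance(toy$traj, toy$system, mode = "ca"), rep(10, 5))
  # glycan chains: innermost atoms 2 A apart; centroids 3 A apart
  expect_equal(glycan_min_distance(toy$traj, toy$system), rep(2, 5))
  gcom <- glycan_min_distance(toy$traj, toy$system, mode = "com")
  expect_equal(gcom, rep(3, 5))
  expect_true(all(glycan_min_distance(toy$traj, toy$system) <= gcom))

  # randomized check against an O(n^2) scan
  set.seed(33)
  tr <- toy$traj
  tr$coords <- tr$coords + array(rnorm(length(tr$coords)), dim = dim(tr$coords))
  g1 <- which(tr$atoms$chain == "E")
  g2 <- which(tr$atoms$chain == "F")
  want <- vapply(1:5, function(f) {
    xyz <- frame_coords(tr, f)
    mn <- Inf
    for (i in g1) for (j in g2)
      mn <- min(mn, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
    mn
  }, numeric(1))
  expect_equal(glycan_min_distance(tr, toy$system), want, tolerance = 1e-9)
})

test_that("descriptors are invariant under per-frame rigid transforms", {
  set.seed(44)
  toy <- make_toy_antibody(toy_antibody_spec(
    cbind(c(70, 80, 95, 60), c(70, 65, 72, 88)),
    cbind(c(0, 30, -50, 120), c(10, -20, 40, -90))))
  d0 <- fab_descriptors(toy$traj, toy$system)
  d1 <- fab_descriptors(apply_rigid(toy$traj), toy$system)
  for (col in c("theta1", "theta2", "phi1", "phi2", "inter_fab_angle",
                "ch2_distance", "glycan_distance")) {
    expect_equal(d1[[col]], d0[[col]], tolerance = 1e-6)
  }
  expect_identical(d1$shape, d0$shape)
})
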