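# correlation: DCCM and domain-block summaries.

# Trajectory with a static scaffold plus two probe atoms at the scaffold
# centroid whose displacements are exactly equal (or opposite). With the
# scaffold static and the probes mirrored, the optimal fit is exactly the
# identity (zero net translation, symmetric cross-covariance), so the
# expected probe correlations are exact. The static scaffold atoms are
# zero-variance and get masked with a warning, which the tests expect.
probe_traj <- function(nf = 40, anti = FALSE, jitter_sd = 0) {
  scaffold <- rbind(diag(3) * 10, -diag(3) * 10,
                    matrix(c(7, 7, 7, -7, 7, -7, 7, -7, -7, -7, -7, 7), 4, 3,
                           byrow = TRUE))
  n <- nrow(scaffold) + 2
  top <- atoms_topology(n)
  coords <- array(NA_real_, dim = c(nf, n, 3))
  set.seed(77)
  for (f in seq_len(nf)) {
    d <- c(sin(f), cos(2 * f), sin(3 * f)) * 0.5
    jit <- if (jitter_sd > 0)
      matrix(rnorm(nrow(scaffold) * 3, 0, jitter_sd), ncol = 3) else 0
    coords[f, 1:nrow(scaffold), ] <- scaffold + jit
    coords[f, n - 1, ] <- d
    coords[f, n, ] <- if (anti) -d else d
  }
  traj_from(top, coords)
}

test_that("DCCM is symmetric with unit diagonal and exact probe correlations", {
  # probes sit at the scaffold centroid with displacements +-d: whatever
  # rigid fit each frame receives, the two probe deviation series stay
  # exactly equal (or exactly opposite), so the correlations are exact
  tr <- probe_traj(anti = FALSE)
  suppressWarnings(dc <- dccm(tr))
  n <- nrow(dc$map)
  expect_equal(dc$map, t(dc$map), tolerance = 1e-12)
  expect_equal(diag(dc$map)[(n - 1):n], c(1, 1))
  expect_true(all(dc$map >= -1 - 1e-12 & dc$map <= 1 + 1e-12, na.rm = TRUE))
  expect_equal(dc$map[n - 1, n], 1, tolerance = 1e-9)

  suppressWarnings(dca <- dccm(probe_traj(anti = TRUE)))
  expect_equal(dca$map[n - 1, n], -1, tolerance = 1e-9)
})

test_that("DCCM is invariant under global rigid motion of all frames", {
  tr <- probe_traj(nf = 25, jitter_sd = 0.05)
  dc0 <- dccm(tr)
  dc1 <- dccm(apply_rigid(tr))
  expect_equal(dc1$map, dc0$map, tolerance = 1e-6)
})

test_that("independent fluctuations give near-zero off-diagonal correlations", {
  set.seed(78)
  n <- 30; nf <- 2000
  base <- matrix(rnorm(n * 3, 0, 10), n, 3)
  coords <- array(NA_real_, dim = c(nf, n, 3))
  for (f in seq_len(nf))
    coords[f, , ] <- base + matrix(rnorm(n * 3, 0, 0.3), n, 3)
  dc <- dccm(traj_from(atoms_topology(n), coords))
  off <- abs(dc$map[upper.tri(dc$map)])
  expect_gt(mean(off < 0.1), 0.99)
})

test_that("block summary recovers block-constant maps and classifies halves", {
  # hand-built map over two domains per chain label
  labs <- data.frame(
    chain = rep(c("A", "B", "C", "D"), each = 4),
    resid = rep(1:4, 4),
    label = rep(c("LC1", "LC2", "HC1", "HC2"), each = 4),
    domain = rep(rep(c("VL", "CL"), each = 2), 4), stringsAsFactors = FALSE)
  labs$domain[labs$label %in% c("HC1", "HC2")] <-
    rep(rep(c("VH", "CH2"), each = 2), 2)
  n <- nrow(labs)
  map <- diag(n)
  block <- paste(labs$label, labs$domain)
  set_block <- function(map, a, b, v) {
    ia <- which(block == a); ib <- which(block == b)
    map[ia, ib] <- v; map[ib, ia] <- v
    map
  }
  map <- set_block(map, "HC1 VH", "HC1 CH2", 0.9)   # intra-chain
  map <- set_block(map, "LC1 VL", "HC1 VH", 0.7)    # inter-chain (same half)
  map <- set_block(map, "LC1 CL", "LC2 VL", 0.85)   # inter-halves
  dc <- structure(list(map = map, labels = labs), class = "fd_dccm")
  bs <- domain_block_summary(dc, threshold = 0.5)

  row_of <- function(a, b) {
    hit <- (bs$block_a == a & bs$block_b == b) |
           (bs$block_a == b & bs$block_b == a)
    bs[hit, ]
  }
  r1 <- row_of("HC1.VH", "HC1.CH2")
  expect_equal(r1$mean_correlation, 0.9)
  expect_equal(r1$class, "intra-chain")
  expect_true(r1$strong)
  r2 <- row_of("LC1.VL", "HC1.VH")
  expect_equal(r2$mean_correlation, 0.7)
  expect_equal(r2$class, "inter-chain")
  expect_true(r2$strong)
  r3 <- row_of("LC1.CL", "LC2.VL")
  expect_equal(r3$mean_correlation, 0.85)
  expect_equal(r3$class, "inter-halves")
  expect_true(r3$strong)
  # identity-like blocks: off-diagonal means are 0, nothing else flagged
  r4 <- row_of("LC2.CL", "HC2.CH2")
  expect_equal(r4$mean_correlation, 0)
  expect_false(r4$strong)

  labs2 <- labs; labs2$domain[1] <- NA
  dc2 <- structure(list(map = map, labels = labs2), class = "fd_dccm")
  expect_error(domain_block_summary(dc2), "unlabeled")
})

test_that("zero-variance atoms are reported and masked", {
  set.seed(79)
  n <- 8; nf <- 10
  base <- matrix(rnorm(n * 3, 0, 5), n, 3)
  coords <- array(NA_real_, dim = c(nf, n, 3))
  for (f in seq_len(nf)) coords[f, , ] <- base   # perfectly static system
  expect_warning(dc <- dccm(traj_from(atoms_topology(n), coords)),
                 "zero-variance")
  expect_true(all(is.na(dc$map)))
})
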