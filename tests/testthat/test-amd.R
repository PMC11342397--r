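# amd: boost parameters, Maclaurin weights, FES, minimum-energy frames.

test_that("amd_parameters implements the standard dual-boost recipe", {
  p <- amd_parameters(avg_eptot = -3000, avg_dihed = 500,
                      n_atoms = 1000, n_res = 100)
  expect_equal(p$ethresh_p, -2800)
  expect_equal(p$alpha_p, 200)
  expect_equal(p$ethresh_d, 850)
  expect_equal(p$alpha_d, 70)
  expect_error(amd_parameters(-3000, 500, 1000, 100, c_p = 0, c_d = 0),
               "alpha")
  expect_error(amd_parameters(-3000, 500, -5, 100), "positive")
})

test_that("maclaurin weights match the partial-sum oracle", {
  kt <- 0.0019872041 * 300
  expect_equal(maclaurin_weights(rep(0, 7)), rep(1, 7))
  expect_equal(maclaurin_weights(runif(5, 0, 10), order = 0), rep(1, 5))

  # beta dV = 1 exactly
  w <- maclaurin_weights(kt * 1, temperature = 300, order = 10)
  oracle <- sum(1 / factorial(0:10))
  expect_equal(w, oracle, tolerance = 1e-12)
  expect_lt(abs(w - exp(1)) / exp(1), 1e-7)

  # truncation error shrinks monotonically with order, for beta dV <= 5
  for (x in c(0.5, 1, 2, 5)) {
    errs <- vapply(0:12, function(ord)
      abs(maclaurin_weights(kt * x, order = ord) - exp(x)), numeric(1))
    expect_true(all(diff(errs) < 1e-12))
  }
  expect_error(maclaurin_weights(1, temperature = -1), "temperature")
})

test_that("reweighted_fes handles degenerate and flat inputs", {
  # delta distribution: single occupied bin at PMF 0, everything else masked
  fes <- reweighted_fes(rep(45.1, 50), rep(45.2, 50), bins = 10,
                        range = c(0, 90))
  expect_equal(sum(fes$occupied), 1)
  expect_equal(fes$pmf[fes$occupied], 0)
  expect_true(all(is.na(fes$pmf[!fes$occupied])))

  # exactly uniform occupancy: PMF 0 on every occupied bin
  g <- expand.grid(t1 = c(10, 30, 50), t2 = c(10, 30, 50))
  fes2 <- reweighted_fes(g$t1, g$t2, bins = 4, range = c(0, 80))
  expect_equal(fes2$pmf[fes2$occupied], rep(0, 9))
  # probabilities over occupied bins sum to 1
  expect_equal(sum(fes2$prob[fes2$occupied]), 1)

  expect_error(reweighted_fes(c(1, NA), c(1, 2)), "NaN")
  expect_error(reweighted_fes(c(1, 2), c(1, 2), weights = c(0, 0)), "zero")
})

test_that("zero boost reproduces the unweighted FES bit-for-bit", {
  set.seed(5)
  t1 <- runif(500, 0, 180); t2 <- runif(500, 0, 180)
  w <- maclaurin_weights(rep(0, 500))
  f_w <- reweighted_fes(t1, t2, weights = w, bins = 30)
  f_u <- reweighted_fes(t1, t2, bins = 30)
  expect_identical(f_w$pmf, f_u$pmf)
  expect_identical(f_w$wsum, f_u$wsum)
})

test_that("designed harmonic PMF is recovered from a flattened ensemble", {
  pmf <- designed_pmf()
  ens <- simulate_boosted_ensemble(pmf, n_frames = 50000, seed = 7)
  w <- maclaurin_weights(ens$boost)
  fes <- reweighted_fes(ens$theta$theta1, ens$theta$theta2, weights = w,
                        bins = 20, range = pmf$range)
  centers <- (fes$edges1[-1] + fes$edges1[-length(fes$edges1)]) / 2
  truth <- outer(centers, centers, pmf$fun)
  well <- fes$counts >= 50
  truth <- truth - min(truth[well])
  expect_gt(sum(well), 100)
  expect_lt(max(abs(fes$pmf[well] - truth[well])), 0.3)
})

test_that("minimum_energy_frames agrees with a per-frame brute-force scan", {
  pmf <- designed_pmf(centers = c(55, 85), range = c(30, 110))
  ens <- simulate_boosted_ensemble(pmf, n_frames = 4000, seed = 9)
  w <- maclaurin_weights(ens$boost)
  fes <- reweighted_fes(ens$theta$theta1, ens$theta$theta2, weights = w,
                        bins = 16, range = pmf$range)
  sel <- minimum_energy_frames(fes, ens$theta$theta1, ens$theta$theta2, 0.5)
  # oracle: locate each frame's bin by explicit comparison with the edges
  oracle <- integer(0)
  for (i in seq_len(4000)) {
    b1 <- b2 <- NA
    for (k in seq_len(length(fes$edges1) - 1)) {
      if (ens$theta$theta1[i] >= fes$edges1[k] && ens$theta$theta1[i] <= fes$edges1[k + 1] &&
          (ens$theta$theta1[i] < fes$edges1[k + 1] || k == length(fes$edges1) - 1)) b1 <- k
      if (ens$theta$theta2[i] >= fes$edges2[k] && ens$theta$theta2[i] <= fes$edges2[k + 1] &&
          (ens$theta$theta2[i] < fes$edges2[k + 1] || k == length(fes$edges2) - 1)) b2 <- k
    }
    if (!is.na(b1) && !is.na(b2) && !is.na(fes$pmf[b1, b2]) &&
        fes$pmf[b1, b2] < 0.5) oracle <- c(oracle, i)
  }
  expect_identical(sel, oracle)
  expect_true(all(diff(sel) > 0))       # order preserved
  expect_error(minimum_energy_frames(fes, 1, 1, pmf_threshold = 0), "> 0")
})

test_that("PMF values are non-negative and masked bins never selected", {
  set.seed(6)
  t1 <- rnorm(2000, 90, 15); t2 <- rnorm(2000, 90, 15)
  fes <- reweighted_fes(t1, t2, bins = 25)
  expect_true(all(fes$pmf[fes$occupied] >= 0))
  sel <- minimum_energy_frames(fes, t1, t2, 0.5)
  b1 <- findInterval(t1[sel], fes$edges1, rightmost.closed = TRUE)
  b2 <- findInterval(t2[sel], fes$edges2, rightmost.closed = TRUE)
  expect_true(all(fes$occupied[cbind(b1, b2)]))
})
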