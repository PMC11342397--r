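# Independent oracles and fixture builders shared across tests. These are
# deliberately written with different algorithms / naive loops than the
# package implementations they check.

# Random proper rotation (QR with det fixed to +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Apply a rigid transform (one rotation/translation per frame) to a traj.
apply_rigid <- function(traj, per_frame = TRUE) {
  coords <- traj$coords
  nf <- dim(coords)[1]
  for (f in seq_len(nf)) {
    r <- random_rotation()
    tr <- rnorm(3, 0, 50)
    coords[f, , ] <- sweep(coords[f, , ] %*% t(r), 2, tr, `+`)
    if (!per_frame && f == 1) { rr <- r; tt <- tr }
  }
  trajectory_slice(coords, traj$atoms, traj$frame_index)
}

# Minimum RMSD via Horn's quaternion method (independent of the package's
# SVD-based Kabsch).
horn_rmsd <- function(p, q) {
  p0 <- sweep(p, 2, colMeans(p))
  q0 <- sweep(q, 2, colMeans(q))
  m <- crossprod(p0, q0)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy, szx - sxz, sxy - syx,
    syz - szy, sxx - syy - szz, sxy + syx, szx + sxz,
    szx - sxz, sxy + syx, -sxx + syy - szz, syz + szy,
    sxy - syx, szx + sxz, syz + szy, -sxx - syy + szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(p0^2) + sum(q0^2) - 2 * lam) / nrow(p)
  sqrt(max(msd, 0))
}

# Exhaustive greedy GROMOS clustering oracle: recompute neighbour counts
# from scratch with explicit loops at every step.
gromos_oracle <- function(m, cutoff, max_clusters) {
  n <- nrow(m)
  left <- seq_len(n)
  assign <- rep(NA_integer_, n)
  medoids <- integer(0)
  cid <- 0L
  while (length(left) > 0 && cid < max_clusters) {
    best <- NA_integer_; best_count <- -1L
    for (i in left) {
      cnt <- 0L
      for (j in left) if (m[i, j] < cutoff) cnt <- cnt + 1L
      if (cnt > best_count) { best_count <- cnt; best <- i }
    }
    cid <- cid + 1L
    members <- left[vapply(left, function(j) m[best, j] < cutoff, logical(1))]
    assign[members] <- cid
    medoids[cid] <- best
    left <- setdiff(left, members)
  }
  sizes <- as.integer(table(factor(assign, levels = seq_len(cid))))
  ord <- order(-sizes, seq_len(cid))
  remap <- integer(cid); remap[ord] <- seq_len(cid)
  list(cluster = remap[assign], medoids = medoids[ord], sizes = sizes[ord])
}

# Random symmetric distance matrix with zero diagonal.
random_dist_matrix <- function(n, scale = 10) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0, scale)
  m + t(m)
}

# Convenience: toy antibody with constant schedules.
const_toy <- function(theta1, theta2, phi1 = 0, phi2 = 0, n = 5, ...) {
  make_toy_antibody(toy_antibody_spec(
    theta_schedule = cbind(rep(theta1, n), rep(theta2, n)),
    phi_schedule = cbind(rep(phi1, n), rep(phi2, n)), ...))
}

# Two-residue backbone (too short for any helix/sheet pattern).
build_dipeptide <- function() fabdyn:::build_backbone(2, phi = -57, psi = -47)

# Bare topology of n carbon pseudo-atoms (one residue each).
atoms_topology <- function(n, chain = "A", name = "CA") {
  data.frame(serial = seq_len(n), name = name, resname = "GLY",
             chain = chain, resid = seq_len(n),
             x = 0, y = 0, z = 0, element = "C", stringsAsFactors = FALSE)
}

# Trajectory from explicit coordinates over a fixture topology.
traj_from <- function(top, coords) {
  atoms <- top
  attr(atoms, "frames") <- NULL
  class(atoms) <- "data.frame"
  trajectory_slice(coords, atoms)
}

# Single/constant-frame trajectory from a topology (mirrors the internal
# helper, kept separate so tests do not rely on unexported code).
fixture_traj <- function(top, n_frames = 1L) {
  xyz <- as.matrix(top[, c("x", "y", "z")])
  coords <- array(NA_real_, dim = c(n_frames, nrow(top), 3))
  for (f in seq_len(n_frames)) coords[f, , ] <- xyz
  traj_from(top, coords)
}
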