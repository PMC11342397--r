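# Seed-deterministic synthetic systems with known ground truth.
#
# Two generators: a coarse Calpha-resolution four-chain pseudo-antibody whose
# Fab arms follow prescribed (theta, phi) schedules, and a grid sampler that
# draws (theta1, theta2) ensembles from a designed analytic free-energy
# surface under a configurable boost, yielding matched boost energies for
# reweighting tests. Small all-atom fixtures (ideal helix, antiparallel
# ladder, donor-H-acceptor triads, sphere sets) back the secondary-structure,
# hydrogen-bond and SASA operators.

#' Specification for the toy antibody generator
#'
#' @param theta_schedule n_frames x 2 matrix of target latitude angles
#'   (degrees) for Fab1 and Fab2.
#' @param phi_schedule n_frames x 2 matrix of target longitudes (degrees).
#' @param residues_per_domain Calpha count per domain (default 8).
#' @param arm_length distance from the hinge to each Fab centroid, Angstrom
#'   (default 40, the order of a real Fab arm).
#' @param noise_sigma sd of Gaussian positional noise, Angstrom (default 0).
#' @param seed RNG seed for the noise.
#' @param with_glycans add two Fc glycan pseudo-chains (default TRUE).
#' @return list of class `fd_toy_spec`.
#' @export
toy_antibody_spec <- function(theta_schedule, phi_schedule = NULL,
                              residues_per_domain = 8, arm_length = 40,
                              noise_sigma = 0, seed = 1L,
                              with_glycans = TRUE) {
  theta_schedule <- as.matrix(theta_schedule)
  if (nrow(theta_schedule) == 0) stop_fd("zero-length schedule")
  if (ncol(theta_schedule) != 2) stop_fd("theta_schedule must have 2 columns")
  if (is.null(phi_schedule))
    phi_schedule <- matrix(0, nrow(theta_schedule), 2)
  phi_schedule <- as.matrix(phi_schedule)
  if (!all(dim(phi_schedule) == dim(theta_schedule)))
    stop_fd("theta and phi schedules must have equal dimensions")
  if (noise_sigma < 0) stop_fd("noise_sigma must be >= 0")
  structure(list(theta_schedule = theta_schedule,
                 phi_schedule = phi_schedule,
                 residues_per_domain = as.integer(residues_per_domain),
                 arm_length = arm_length, noise_sigma = noise_sigma,
                 seed = as.integer(seed), with_glycans = with_glycans),
            class = "fd_toy_spec")
}

#' Build a pseudo-antibody system and trajectory from a schedule
#'
#' The generated system has four protein chains (LC1/LC2 = A/B,
#' HC1/HC2 = C/D) at Calpha resolution: a static Fc block (CH2 and CH3 rods
#' per heavy chain), a hinge centred at the origin, and two rigid Fab arms
#' (VH/CH1 on the heavy chain, VL/CL on the light chain) whose Calpha
#' centroids sit exactly at `arm_length` along the scheduled (theta, phi)
#' direction of the Fc-attached frame. Anchor pseudo-atoms mirror the
#' descriptor anchors of a real antibody: the arm-tip VAL Calpha (CDRH1
#' stand-in), an SG atom on the central hinge residue (hinge disulfide
#' stand-in), and an ASN Calpha in each CH2 rod (Fc glycosylation-site
#' stand-in). By construction the geometry module recovers the input
#' schedules exactly on noise-free output.
#'
#' @param spec an `fd_toy_spec`.
#' @return list with `system` (an `fd_system`), `traj` (an `fd_traj` over all
#'   atoms), and `topology`.
#' @export
make_toy_antibody <- function(spec) {
  stopifnot(inherits(spec, "fd_toy_spec"))
  m <- spec$residues_per_domain
  h <- 5L                                 # hinge residues per heavy chain
  nf <- nrow(spec$theta_schedule)

  rows <- list()
  add <- function(name, resname, chain, resid, xyz, element) {
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = length(rows) + 1L, name = name, resname = resname,
      chain = chain, resid = resid, x = xyz[1], y = xyz[2], z = xyz[3],
      element = element, stringsAsFactors = FALSE)
  }

  rod_offsets <- function(n, step) (seq_len(n) - (n + 1) / 2) * step
  hc_chain <- c(HC1 = "C", HC2 = "D")
  lc_chain <- c(LC1 = "A", LC2 = "B")
  sgn <- c(HC1 = 1, HC2 = -1)

  # heavy-chain residue numbering: VH 1..m, CH1 m+1..2m, hinge, CH2, CH3
  hinge_start <- 2L * m + 1L
  ch2_start <- hinge_start + h
  ch3_start <- ch2_start + m
  asn_j <- ceiling(m / 2)

  # ---- static Fc + hinge (identical in every frame, before noise)
  for (lab in c("HC1", "HC2")) {
    s <- sgn[[lab]]
    ch <- hc_chain[[lab]]
    off <- rod_offsets(h, 1.0)
    for (j in seq_len(h)) {
      add("CA", "GLY", ch, hinge_start + j - 1L, c(0.5 * s, off[j], 0), "C")
      if (lab == "HC1" && j == 3L)
        add("SG", "CYS", ch, hinge_start + j - 1L, c(0, 0, 0), "S")
    }
    off <- rod_offsets(m, 1.2)
    for (j in seq_len(m))
      add("CA", if (j == asn_j) "ASN" else "GLY", ch, ch2_start + j - 1L,
          c(5 * s, 0, -10 + off[j]), "C")
    for (j in seq_len(m))
      add("CA", "GLY", ch, ch3_start + j - 1L, c(5 * s, 0, -20 + off[j]), "C")
  }
  if (spec$with_glycans) {
    for (k in 1:5) add(paste0("C", k), "NAG", "E", 1L,
                       c(1.0 + 0.25 * (k - 1), 0, -10), "C")
    for (k in 1:5) add(paste0("C", k), "NAG", "F", 1L,
                       c(-1.0 - 0.25 * (k - 1), 0, -10), "C")
  }

  # ---- Fab arm atoms: positions filled per frame; register rows now.
  # Offsets along the arm ray sum to zero so the four-domain Calpha centroid
  # sits exactly at arm_length.
  s_off <- seq(-10, 10, length.out = 4L * m)
  s_off <- s_off - mean(s_off)
  arm_rows <- list()   # per arm: data.frame(atom_row, t)
  for (arm in 1:2) {
    hc_lab <- paste0("HC", arm); lc_lab <- paste0("LC", arm)
    blocks <- list(
      list(chain = hc_chain[[hc_lab]], resid0 = m,      s = s_off[1:m],                 dom = "CH1"),
      list(chain = lc_chain[[lc_lab]], resid0 = 0L,     s = s_off[(m + 1):(2 * m)],     dom = "VL"),
      list(chain = lc_chain[[lc_lab]], resid0 = m,      s = s_off[(2 * m + 1):(3 * m)], dom = "CL"),
      list(chain = hc_chain[[hc_lab]], resid0 = 0L,     s = s_off[(3 * m + 1):(4 * m)], dom = "VH"))
    recs <- list()
    for (b in blocks) {
      for (j in seq_len(m)) {
        resid <- b$resid0 + j
        resname <- if (b$dom == "VH" && j == m) "VAL" else "GLY"
        add("CA", resname, b$chain, resid, c(0, 0, 0), "C")
        recs[[length(recs) + 1L]] <-
          data.frame(row = length(rows), t = spec$arm_length + b$s[j])
      }
    }
    arm_rows[[arm]] <- do.call(rbind, recs)
  }

  top <- do.call(rbind, rows)
  class(top) <- c("fd_topology", "data.frame")
  na <- nrow(top)

  coords <- array(NA_real_, dim = c(nf, na, 3))
  base <- as.matrix(top[, c("x", "y", "z")])
  for (f in seq_len(nf)) {
    xyz <- base
    for (arm in 1:2) {
      th <- rad(spec$theta_schedule[f, arm])
      ph <- rad(spec$phi_schedule[f, arm])
      d <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      ar <- arm_rows[[arm]]
      xyz[ar$row, ] <- outer(ar$t, d)
    }
    coords[f, , ] <- xyz
  }
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    coords <- coords + array(stats::rnorm(length(coords), 0, spec$noise_sigma),
                             dim = dim(coords))
  }

  dr <- rbind(
    data.frame(label = "HC1", domain = c("VH", "CH1", "hinge", "CH2", "CH3"),
               start = c(1L, m + 1L, hinge_start, ch2_start, ch3_start),
               end = c(m, 2L * m, hinge_start + h - 1L, ch2_start + m - 1L,
                       ch3_start + m - 1L)),
    data.frame(label = "HC2", domain = c("VH", "CH1", "hinge", "CH2", "CH3"),
               start = c(1L, m + 1L, hinge_start, ch2_start, ch3_start),
               end = c(m, 2L * m, hinge_start + h - 1L, ch2_start + m - 1L,
                       ch3_start + m - 1L)),
    data.frame(label = c("LC1", "LC1", "LC2", "LC2"),
               domain = c("VL", "CL", "VL", "CL"),
               start = c(1L, m + 1L, 1L, m + 1L),
               end = c(m, 2L * m, m, 2L * m)))

  hinge_res <- hinge_start:(hinge_start + h - 1L)
  rsets <- list(
    hinge = rbind(data.frame(label = "HC1", resid = hinge_res),
                  data.frame(label = "HC2", resid = hinge_res)),
    fcgr3a_site = rbind(data.frame(label = "HC1", resid = ch2_start:(ch2_start + 2L)),
                        data.frame(label = "HC2", resid = ch2_start:(ch2_start + 2L))),
    fcrn_site = rbind(data.frame(label = "HC1", resid = ch3_start:(ch3_start + 2L)),
                      data.frame(label = "HC2", resid = ch3_start:(ch3_start + 2L))))

  anchors <- list(
    val34_hc1 = list(label = "HC1", resid = m, atom = "CA"),
    val34_hc2 = list(label = "HC2", resid = m, atom = "CA"),
    cys228_sg = list(label = "HC1", resid = hinge_start + 2L, atom = "SG"),
    asn299_hc1 = list(label = "HC1", resid = ch2_start + asn_j - 1L, atom = "CA"),
    asn299_hc2 = list(label = "HC2", resid = ch2_start + asn_j - 1L, atom = "CA"))

  glycans <- if (spec$with_glycans)
    list(fc_glycan_1 = list(chain = "E", resid = NULL),
         fc_glycan_2 = list(chain = "F", resid = NULL)) else list()

  system <- annotated_system(
    chain_map = c(LC1 = "A", LC2 = "B", HC1 = "C", HC2 = "D"),
    domain_ranges = dr, glycans = glycans, residue_sets = rsets,
    anchors = anchors)

  atoms <- top
  attr(atoms, "frames") <- NULL
  class(atoms) <- "data.frame"
  list(system = system,
       traj = trajectory_slice(coords, atoms),
       topology = top)
}

# ------------------------------------------------------------- designed PMF

#' Designed analytic free-energy surface over (theta1, theta2)
#'
#' Sum of two one-dimensional harmonic wells,
#' `PMF = k1/2 (theta1 - c1)^2 + k2/2 (theta2 - c2)^2` (kcal/mol, angles in
#' degrees), restricted to a rectangular domain. The minimum is 0 by
#' construction.
#'
#' @param centers length-2 well positions, degrees (default c(70, 70)).
#' @param curvatures length-2 force constants, kcal/mol/deg^2 (default 0.004,
#'   i.e. ~1.8 kcal/mol at 30 degrees from the well).
#' @param range length-2 domain bounds applied to both angles (default
#'   c(40, 100)).
#' @param temperature Kelvin (default 300).
#' @return object of class `fd_designed_pmf` with an evaluator `fun(t1, t2)`.
#' @export
designed_pmf <- function(centers = c(70, 70), curvatures = c(0.004, 0.004),
                         range = c(40, 100), temperature = 300) {
  force(centers); force(curvatures)
  fun <- function(t1, t2)
    0.5 * curvatures[1] * (t1 - centers[1])^2 +
    0.5 * curvatures[2] * (t2 - centers[2])^2
  structure(list(fun = fun, centers = centers, curvatures = curvatures,
                 range = range, temperature = temperature),
            class = "fd_designed_pmf")
}

#' Sample a boosted ensemble from a designed PMF
#'
#' Emulates the output of an accelerated-MD run on the designed surface:
#' samples (theta1, theta2) from the boosted density
#' `exp(-(PMF + dV)/kT)` on a fine grid (inverse-CDF draw of a cell followed
#' by a uniform jitter within the cell), with the matching boost energy dV
#' per sample. In accelerated MD the boost raises the potential inside wells,
#' so a flattening boost is `dV = c * (max(PMF) - PMF)`: with `c = 1` the
#' boosted ensemble is exactly uniform over the domain, and frame weights
#' `exp(dV/kT)` recover the designed surface.
#'
#' @param pmf an `fd_designed_pmf`.
#' @param boost either a list `list(type = "flatten", c = 1)` or a function
#'   `f(theta1, theta2)` returning a non-negative boost (kcal/mol).
#' @param n_frames number of samples.
#' @param seed RNG seed.
#' @param grid_step grid resolution in degrees (default 0.5).
#' @return list with `theta` (data.frame theta1, theta2), `boost`
#'   (an `fd_boost`), and `pmf` (the ground truth).
#' @export
simulate_boosted_ensemble <- function(pmf, boost = list(type = "flatten", c = 1),
                                      n_frames = 1000L, seed = 1L,
                                      grid_step = 0.5) {
  stopifnot(inherits(pmf, "fd_designed_pmf"))
  if (n_frames < 1) stop_fd("n_frames must be >= 1")
  kt <- KB_KCAL * pmf$temperature
  lo <- pmf$range[1]; hi <- pmf$range[2]
  centers <- seq(lo + grid_step / 2, hi - grid_step / 2, by = grid_step)
  g <- expand.grid(t1 = centers, t2 = centers)
  pmf_g <- pmf$fun(g$t1, g$t2)

  boost_fun <- if (is.function(boost)) {
    boost
  } else if (identical(boost$type, "flatten")) {
    # supremum over the closed domain (boundary included), so jittered
    # samples near the edges never see a negative boost
    bgrid <- seq(lo, hi, length.out = 201)
    bg <- expand.grid(t1 = bgrid, t2 = bgrid)
    cmax <- max(pmf$fun(bg$t1, bg$t2))
    cc <- boost$c %||% 1
    function(t1, t2) cc * pmax(cmax - pmf$fun(t1, t2), 0)
  } else stop_fd("unknown boost spec")

  dv_g <- boost_fun(g$t1, g$t2)
  if (any(dv_g < -1e-9)) stop_fd("boost function produced negative dV")
  log_dens <- -(pmf_g + dv_g) / kt
  dens <- exp(log_dens - max(log_dens))
  set.seed(seed)
  cells <- sample.int(nrow(g), n_frames, replace = TRUE, prob = dens)
  t1 <- g$t1[cells] + stats::runif(n_frames, -grid_step / 2, grid_step / 2)
  t2 <- g$t2[cells] + stats::runif(n_frames, -grid_step / 2, grid_step / 2)
  dv <- boost_fun(t1, t2)
  list(theta = data.frame(theta1 = t1, theta2 = t2),
       boost = boost_series(dv), pmf = pmf)
}

# --------------------------------------------------------- all-atom fixtures

# NeRF placement: position d with |c-d| = bond, angle(b,c,d) = ang (deg),
# torsion(a,b,c,d) = tors (deg).
place_atom <- function(a, b, c, bond, ang, tors) {
  ang <- rad(ang); tors <- rad(tors)
  bc <- unitv(c - b)
  n <- unitv(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tors), sin(ang) * sin(tors))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Build an ideal poly-alanine backbone (N, CA, C, O, amide H) from phi/psi.
build_backbone <- function(n_res, phi, psi, chain = "A") {
  omega <- 180
  bN_CA <- 1.458; bCA_C <- 1.525; bC_N <- 1.329; bC_O <- 1.231
  aC_N_CA <- 121.7; aN_CA_C <- 111.2; aCA_C_N <- 116.2; aCA_C_O <- 120.5
  pos <- list()
  # seed triad
  pos[["N1"]] <- c(0, 0, 0)
  pos[["CA1"]] <- c(bN_CA, 0, 0)
  th <- rad(180 - aN_CA_C)
  pos[["C1"]] <- pos[["CA1"]] + bCA_C * c(cos(th), sin(th), 0)
  for (i in seq_len(n_res)) {
    Ni <- pos[[paste0("N", i)]]; CAi <- pos[[paste0("CA", i)]]
    Ci <- pos[[paste0("C", i)]]
    if (i < n_res) {
      Nn <- place_atom(Ni, CAi, Ci, bC_N, aCA_C_N, psi)
      pos[[paste0("N", i + 1)]] <- Nn
      CAn <- place_atom(CAi, Ci, Nn, bN_CA, aC_N_CA, omega)
      pos[[paste0("CA", i + 1)]] <- CAn
      Cn <- place_atom(Ci, Nn, CAn, bCA_C, aN_CA_C, phi)
      pos[[paste0("C", i + 1)]] <- Cn
      # carbonyl O: anti to the next N across the sp2 carbon
      pos[[paste0("O", i)]] <- place_atom(Nn, CAi, Ci, bC_O, aCA_C_O, 180)
    } else {
      pos[[paste0("O", i)]] <- place_atom(Ni, CAi, Ci, bC_O, aCA_C_O, psi + 180)
    }
  }
  # amide H: in-plane bisector of C(i-1)-N and CA-N, 0.98 A from N
  for (i in 2:n_res) {
    Ni <- pos[[paste0("N", i)]]
    Cp <- pos[[paste0("C", i - 1)]]
    CAi <- pos[[paste0("CA", i)]]
    hdir <- unitv(unitv(Ni - Cp) + unitv(Ni - CAi))
    pos[[paste0("H", i)]] <- Ni + 0.98 * hdir
  }
  rows <- list()
  serial <- 0L
  for (i in seq_len(n_res)) {
    for (nm in c("N", "H", "CA", "C", "O")) {
      key <- paste0(nm, i)
      if (is.null(pos[[key]])) next
      serial <- serial + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        serial = serial, name = nm, resname = "ALA", chain = chain,
        resid = i, x = pos[[key]][1], y = pos[[key]][2], z = pos[[key]][3],
        element = substr(nm, 1, 1), stringsAsFactors = FALSE)
    }
  }
  top <- do.call(rbind, rows)
  class(top) <- c("fd_topology", "data.frame")
  top
}

# Hand-designed antiparallel two-strand ladder: every paired residue donates
# and accepts across the strands (idealized; used only to exercise the
# bridge/ladder logic of the secondary-structure operator).
build_antiparallel_sheet <- function(n_res = 6, sep = 4.13) {
  rows <- list(); serial <- 0L
  add <- function(nm, chain, resid, xyz) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = nm, resname = "ALA", chain = chain,
      resid = resid, x = xyz[1], y = xyz[2], z = xyz[3],
      element = substr(nm, 1, 1), stringsAsFactors = FALSE)
  }
  step <- 3.5
  for (i in seq_len(n_res)) {          # strand A at y = 0, runs +x
    x <- step * i
    add("N", "A", i, c(x, 0, 0))
    add("H", "A", i, c(x, 1.0, 0))
    add("CA", "A", i, c(x + 1.0, -0.8, 0))
    add("C", "A", i, c(x + 1.75, 0.2, 0))
    add("O", "A", i, c(x + 1.75, 1.43, 0))
  }
  for (j in seq_len(n_res)) {          # strand B at y = sep, runs -x
    # offset so residue j of B sits H-bond-aligned above residue n-j of A
    x <- step * (n_res - j) + 1.75
    add("N", "B", j, c(x, sep, 0))
    add("H", "B", j, c(x, sep - 1.0, 0))
    add("CA", "B", j, c(x - 1.0, sep + 0.8, 0))
    add("C", "B", j, c(x - 1.75, sep - 0.2, 0))
    add("O", "B", j, c(x - 1.75, sep - 1.43, 0))
  }
  top <- do.call(rbind, rows)
  class(top) <- c("fd_topology", "data.frame")
  top
}

# Donor-H-acceptor triad at a parameterized H...A distance and D-H...A angle.
build_hbond_triad <- function(ha_distance = 1.8, dha_angle = 180) {
  a <- rad(dha_angle)
  H <- c(1.0, 0, 0)
  # direction from H making angle `dha_angle` with the H->donor vector
  dirA <- c(-cos(a), sin(a), 0)
  A <- H + ha_distance * dirA
  rows <- data.frame(
    serial = 1:3,
    name = c("N", "H", "O"),
    resname = c("ALA", "ALA", "HOH"),
    chain = c("A", "A", "B"),
    resid = c(1L, 1L, 2L),
    x = c(0, H[1], A[1]), y = c(0, H[2], A[2]), z = c(0, H[3], A[3]),
    element = c("N", "H", "O"), stringsAsFactors = FALSE)
  class(rows) <- c("fd_topology", "data.frame")
  rows
}

# n atoms as a topology, all carbon unless stated.
atoms_at <- function(xyz, element = "C", name = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  rows <- data.frame(
    serial = seq_len(n), name = name %||% rep("X", n),
    resname = "UNK", chain = "A", resid = seq_len(n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = rep(element, length.out = n), stringsAsFactors = FALSE)
  class(rows) <- c("fd_topology", "data.frame")
  rows
}

#' All-atom structural fixtures for interaction operators
#'
#' @return list with components:
#'   `helix` (14-residue ideal alpha helix, phi = -57, psi = -47),
#'   `sheet` (idealized antiparallel two-strand ladder),
#'   `triad(ha_distance, dha_angle)` (donor-H-acceptor topology factory),
#'   `single_atom` (one carbon at the origin),
#'   `two_spheres(d)` (two carbons `d` Angstrom apart),
#'   `caged_atom` (one atom enclosed by a tight shell of neighbours).
#' @export
make_structure_fixtures <- function() {
  corners <- unname(as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))) / sqrt(3)
  cage_dirs <- rbind(diag(3), -diag(3), corners)
  list(
    helix = build_backbone(14, phi = -57, psi = -47),
    sheet = build_antiparallel_sheet(6),
    triad = build_hbond_triad,
    single_atom = atoms_at(c(0, 0, 0)),
    two_spheres = function(d) atoms_at(rbind(c(0, 0, 0), c(d, 0, 0))),
    caged_atom = atoms_at(rbind(c(0, 0, 0), cage_dirs * 2.2))
  )
}

# Single-frame trajectory from a topology's own coordinates.
topology_traj <- function(top, n_frames = 1L) {
  xyz <- as.matrix(top[, c("x", "y", "z")])
  coords <- array(rep(xyz, each = n_frames), dim = c(n_frames, nrow(top), 3))
  atoms <- top
  attr(atoms, "frames") <- NULL
  class(atoms) <- "data.frame"
  trajectory_slice(coords, atoms)
}
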