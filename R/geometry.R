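# Per-frame Fab/Fc geometric descriptors.
#
# All descriptors are computed in an instantaneous reference frame attached
# to the Fc and centred at the hinge, rebuilt for every trajectory frame:
#   origin = Calpha centroid of the hinge;
#   z = unit vector from the Fc Calpha centroid (CH2 + CH3, both heavy
#       chains) toward the origin, i.e. pointing from Fc toward the Fabs;
#   x = component of (CH2-of-HC1 centroid - CH2-of-HC2 centroid) orthogonal
#       to z;
#   y = z cross x (right-handed).
# Each Fab position is the Calpha centroid of its VH+CH1+VL+CL domains,
# expressed as polar angle theta (latitude, from +z) and azimuth phi
# (longitude, atan2 over the x/y components), in degrees.

# Precompute the atom index sets the descriptors need.
geometry_indices <- function(system, atoms) {
  hinge <- c(domain_atoms(system, atoms, "HC1", "hinge"),
             domain_atoms(system, atoms, "HC2", "hinge"))
  ch2_1 <- domain_atoms(system, atoms, "HC1", "CH2")
  ch2_2 <- domain_atoms(system, atoms, "HC2", "CH2")
  ch3 <- c(domain_atoms(system, atoms, "HC1", "CH3"),
           domain_atoms(system, atoms, "HC2", "CH3"))
  fab <- lapply(1:2, function(arm) {
    c(domain_atoms(system, atoms, paste0("HC", arm), "VH"),
      domain_atoms(system, atoms, paste0("HC", arm), "CH1"),
      domain_atoms(system, atoms, paste0("LC", arm), "VL"),
      domain_atoms(system, atoms, paste0("LC", arm), "CL"))
  })
  list(hinge = hinge, ch2_1 = ch2_1, ch2_2 = ch2_2,
       fc = c(ch2_1, ch2_2, ch3), fab = fab)
}

centroid <- function(xyz, idx) colMeans(xyz[idx, , drop = FALSE])

#' Build the instantaneous Fc-attached reference frame
#'
#' @param xyz n_atoms x 3 coordinate matrix for one frame.
#' @param system an `fd_system`.
#' @param atoms topology table matching `xyz`.
#' @return list of class `fd_frame` with `origin` and orthonormal,
#'   right-handed unit axes `x`, `y`, `z`.
#' @export
build_fc_frame <- function(xyz, system, atoms) {
  gi <- geometry_indices(system, atoms)
  build_fc_frame_idx(xyz, gi)
}

build_fc_frame_idx <- function(xyz, gi) {
  origin <- centroid(xyz, gi$hinge)
  fc <- centroid(xyz, gi$fc)
  zax <- origin - fc
  if (vnorm(zax) < 1e-8) stop_fd("degenerate geometry: Fc centroid coincides with hinge")
  zax <- zax / vnorm(zax)
  xraw <- centroid(xyz, gi$ch2_1) - centroid(xyz, gi$ch2_2)
  if (vnorm(xraw) < 1e-8) stop_fd("degenerate geometry: CH2 centroids coincide")
  xax <- xraw - sum(xraw * zax) * zax
  if (vnorm(xax) < 1e-8) stop_fd("degenerate geometry: CH2 axis parallel to Fc axis")
  xax <- xax / vnorm(xax)
  yax <- pracma_cross(zax, xax)
  structure(list(origin = origin, x = xax, y = yax, z = zax),
            class = "fd_frame")
}

#' Per-frame spherical angles of both Fab arms
#'
#' @param traj an `fd_traj` containing all annotated atoms.
#' @param system an `fd_system`.
#' @return data.frame with columns `frame`, `theta1`, `theta2`, `phi1`,
#'   `phi2`, `pole1`, `pole2` (logical: phi reported as 0 at the poles).
#' @export
fab_spherical_angles <- function(traj, system) {
  gi <- geometry_indices(system, traj$atoms)
  nf <- n_frames(traj)
  out <- data.frame(frame = traj$frame_index,
                    theta1 = NA_real_, theta2 = NA_real_,
                    phi1 = NA_real_, phi2 = NA_real_,
                    pole1 = FALSE, pole2 = FALSE)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    fr <- build_fc_frame_idx(xyz, gi)
    for (arm in 1:2) {
      v <- centroid(xyz, gi$fab[[arm]]) - fr$origin
      r <- vnorm(v)
      if (r < 1e-8) stop_fd("Fab %d centroid coincides with the hinge origin", arm)
      ct <- sum(v * fr$z) / r
      theta <- deg(acos(pmin(pmax(ct, -1), 1)))
      px <- sum(v * fr$x); py <- sum(v * fr$y)
      at_pole <- sqrt(px^2 + py^2) / r < 1e-9
      phi <- if (at_pole) 0 else deg(atan2(py, px))
      out[[paste0("theta", arm)]][f] <- theta
      out[[paste0("phi", arm)]][f] <- phi
      out[[paste0("pole", arm)]][f] <- at_pole
    }
  }
  out
}

#' Classify antibody shape from the two Fab latitudes
#'
#' Y-shaped when both Fabs sit below 90 degrees latitude; T-shaped when at
#' least one Fab reaches 90 degrees or beyond.
#'
#' @param theta1,theta2 latitude angles in degrees (vectorized).
#' @return character vector of "Y"/"T".
#' @export
classify_shape <- function(theta1, theta2) {
  if (any(theta1 < 0 | theta1 > 180 | theta2 < 0 | theta2 > 180, na.rm = TRUE))
    stop_fd("theta angles must lie in [0, 180] degrees")
  ifelse(theta1 < 90 & theta2 < 90, "Y", "T")
}

#' Longitude change relative to the starting frame
#'
#' With `unwrap = TRUE` (default) the phi series is first made continuous
#' across the +-180 seam, so cumulative rotations beyond a full turn are
#' representable; otherwise the raw circular difference mapped to
#' (-180, 180] is returned.
#'
#' @param phi_series longitude series in degrees.
#' @param unwrap logical.
#' @return numeric vector of delta-phi values (degrees), first element 0.
#' @export
delta_phi <- function(phi_series, unwrap = TRUE) {
  if (length(phi_series) == 0) stop_fd("empty phi series")
  if (unwrap) {
    u <- unwrap_deg(phi_series)
    u - u[1]
  } else {
    wrap180(phi_series - phi_series[1])
  }
}

#' Angle between the two Fab arms
#'
#' Vertex angle at the hinge anchor (e.g. Cys228 SG) between the two arm-tip
#' anchors (e.g. Val34 Calpha of each heavy chain).
#'
#' @param traj an `fd_traj`.
#' @param system an `fd_system` with anchors `val34_hc1`, `val34_hc2`,
#'   `cys228_sg`.
#' @return numeric vector (degrees), one value per frame.
#' @export
inter_fab_angle <- function(traj, system) {
  i1 <- resolve_anchor(system, traj$atoms, "val34_hc1")
  i2 <- resolve_anchor(system, traj$atoms, "val34_hc2")
  iv <- resolve_anchor(system, traj$atoms, "cys228_sg")
  vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)
    angle_at_vertex(xyz[i1, ], xyz[iv, ], xyz[i2, ])
  }, numeric(1))
}

#' Angle at a vertex between two points (degrees)
#' @param a,v,b coordinates; the angle a-v-b is returned.
#' @export
angle_at_vertex <- function(a, v, b) {
  u <- a - v; w <- b - v
  nu <- vnorm(u); nw <- vnorm(w)
  if (nu < 1e-9 || nw < 1e-9) stop_fd("coincident anchor atoms")
  deg(acos(pmin(pmax(sum(u * w) / (nu * nw), -1), 1)))
}

#' Distance between the Fc glycosylation-site residues of the two CH2 domains
#'
#' Distance between the two annotated Fc-glycosylation residues (anchors
#' `asn299_hc1`/`asn299_hc2`), an indicator of Fc opening. The default uses
#' the heavy-atom centroid of each residue; `mode = "ca"` uses the two
#' anchor atoms directly.
#'
#' @param traj an `fd_traj`.
#' @param system an `fd_system`.
#' @param mode "heavy" (residue heavy-atom centroid, default) or "ca".
#' @return numeric vector (Angstrom), one value per frame.
#' @export
ch2_distance <- function(traj, system, mode = c("heavy", "ca")) {
  mode <- match.arg(mode)
  sets <- lapply(c("asn299_hc1", "asn299_hc2"), function(nm) {
    a <- system$anchors[[nm]]
    if (is.null(a)) stop_fd("missing anchor '%s'", nm)
    ch <- system$chain_map[[a$label]] %||% a$label
    if (mode == "ca") {
      resolve_anchor(system, traj$atoms, nm)
    } else {
      idx <- select_atoms(traj$atoms, chain = ch, resid = a$resid, heavy = TRUE)
      if (length(idx) == 0) stop_fd("anchor residue %s/%d has no heavy atoms", ch, a$resid)
      idx
    }
  })
  vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)
    vnorm(centroid(xyz, sets[[1]]) - centroid(xyz, sets[[2]]))
  }, numeric(1))
}

#' Separation of the two Fc glycan chains
#'
#' `mode = "min"` returns the minimum heavy-atom pair distance between the
#' two glycan selections; `mode = "com"` the distance between their centroids
#' (always >= the minimum-atom value).
#'
#' @param traj an `fd_traj`.
#' @param system an `fd_system` with glycan selections `fc_glycan_1` and
#'   `fc_glycan_2` (names configurable via `which`).
#' @param mode "min" (default) or "com".
#' @param which character vector of the two glycan selection names.
#' @return numeric vector (Angstrom) per frame.
#' @export
glycan_min_distance <- function(traj, system, mode = c("min", "com"),
                                which = c("fc_glycan_1", "fc_glycan_2")) {
  mode <- match.arg(mode)
  g1 <- glycan_atoms(system, traj$atoms, which[1])
  g2 <- glycan_atoms(system, traj$atoms, which[2])
  if (length(g1) == 0 || length(g2) == 0)
    stop_fd("empty glycan selection")
  vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)
    if (mode == "com") {
      vnorm(centroid(xyz, g1) - centroid(xyz, g2))
    } else {
      min(pair_dists(xyz[g1, , drop = FALSE], xyz[g2, , drop = FALSE]))
    }
  }, numeric(1))
}

# All pairwise distances between two coordinate sets (na x nb matrix).
pair_dists <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Full per-frame Fab descriptor table
#'
#' Combines spherical angles, unwrapped delta-phi, the inter-Fab angle, the
#' CH2 distance, the glycan separation, and the Y/T shape label in one tidy
#' table.
#'
#' @param traj an `fd_traj`.
#' @param system an `fd_system`.
#' @param unwrap passed to [delta_phi()].
#' @param glycan_mode passed to [glycan_min_distance()]; skipped when the
#'   system annotates no glycans.
#' @return data.frame (one row per frame).
#' @export
fab_descriptors <- function(traj, system, unwrap = TRUE, glycan_mode = "min") {
  ang <- fab_spherical_angles(traj, system)
  ang$dphi1 <- delta_phi(ang$phi1, unwrap = unwrap)
  ang$dphi2 <- delta_phi(ang$phi2, unwrap = unwrap)
  ang$inter_fab_angle <- inter_fab_angle(traj, system)
  ang$ch2_distance <- ch2_distance(traj, system)
  ang$glycan_distance <- if (length(system$glycans) >= 2)
    glycan_min_distance(traj, system, mode = glycan_mode) else NA_real_
  ang$shape <- classify_shape(ang$theta1, ang$theta2)
  ang
}
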