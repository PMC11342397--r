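# Shrake-Rupley solvent-accessible surface area.

# van der Waals radii (Angstrom) by element; the fallback is carbon-like and
# triggers a warning so silent misassignment cannot happen.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, CL = 1.75, BR = 1.85)
VDW_DEFAULT <- 1.70

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area per atom and per residue
#'
#' Shrake-Rupley rolling-probe algorithm: each atom's sphere (van der Waals
#' radius + probe) is sampled with a deterministic golden-spiral point set;
#' the accessible fraction of points gives the atom's area.
#'
#' @param traj an `fd_traj`.
#' @param selection optional atom indices (default all atoms).
#' @param probe_radius Angstrom (default 1.4, a water molecule).
#' @param n_sphere_points default 960.
#' @param radii optional named vector overriding element radii.
#' @return object of class `fd_sasa`: list with `atom` (atoms x frames
#'   matrix, Angstrom^2), `residue` (data.frame chain, resid, resname, one
#'   `frame_*` column per frame plus `mean_sasa`).
#' @export
sasa <- function(traj, selection = NULL, probe_radius = 1.4,
                 n_sphere_points = 960L, radii = NULL) {
  atoms <- traj$atoms
  sel <- selection %||% seq_len(nrow(atoms))
  el <- toupper(atoms$element[sel])
  rtab <- VDW_RADII
  if (!is.null(radii)) rtab[names(radii)] <- radii
  r <- rtab[el]
  if (any(is.na(r))) {
    warning(sprintf("unknown element radii for: %s (using %.2f A)",
                    paste(unique(el[is.na(r)]), collapse = ", "), VDW_DEFAULT))
    r[is.na(r)] <- VDW_DEFAULT
  }
  r <- unname(r) + probe_radius
  pts <- sphere_points(n_sphere_points)
  nf <- n_frames(traj)
  n <- length(sel)
  area <- matrix(0, n, nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)[sel, , drop = FALSE]
    d <- pair_dists(xyz, xyz)
    for (i in seq_len(n)) {
      neigh <- which(d[i, ] < r[i] + r & seq_len(n) != i)
      surf <- sweep(pts * r[i], 2, xyz[i, ], `+`)
      acc <- rep(TRUE, n_sphere_points)
      for (j in neigh) {
        dj2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
               (surf[, 3] - xyz[j, 3])^2
        acc <- acc & dj2 > r[j]^2
        if (!any(acc)) break
      }
      area[i, f] <- 4 * pi * r[i]^2 * mean(acc)
    }
  }
  key <- paste(atoms$chain[sel], atoms$resid[sel], sep = "_")
  ukey <- unique(key)
  tmp <- vapply(ukey, function(k)
    colSums(area[key == k, , drop = FALSE]), numeric(nf))
  res_area <- if (nf == 1) matrix(tmp, ncol = 1) else t(tmp)
  first <- match(ukey, key)
  residue <- data.frame(chain = atoms$chain[sel][first],
                        resid = atoms$resid[sel][first],
                        resname = atoms$resname[sel][first],
                        stringsAsFactors = FALSE)
  colnames(res_area) <- paste0("frame_", seq_len(nf))
  residue <- cbind(residue, as.data.frame(res_area))
  residue$mean_sasa <- rowMeans(res_area)
  rownames(residue) <- NULL
  structure(list(atom = area, residue = residue, selection = sel,
                 probe_radius = probe_radius),
            class = "fd_sasa")
}

#' Per-frame SASA summed over a named residue set
#'
#' @param sasa_result an `fd_sasa` computed over the full system.
#' @param traj the same trajectory.
#' @param system an `fd_system`.
#' @param set_name residue-set name (e.g. "hinge", "fcgr3a_site").
#' @return numeric vector, one total area per frame.
#' @export
region_sasa <- function(sasa_result, traj, system, set_name) {
  idx <- residue_set_atoms(system, traj$atoms, set_name, heavy = FALSE)
  pos <- match(idx, sasa_result$selection)
  if (any(is.na(pos)))
    stop_fd("residue set '%s' includes atoms outside the SASA selection", set_name)
  colSums(sasa_result$atom[pos, , drop = FALSE])
}
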