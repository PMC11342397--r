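# Geometric hydrogen-bond detection with per-triplet frequencies.

#' Hydrogen bonds over a trajectory
#'
#' Baker-Hubbard-style geometric rule: a donor-H...acceptor triplet counts in
#' a frame when the H...acceptor distance is below `dist_cutoff` and the
#' D-H...A angle exceeds `angle_cutoff`. Donors are N/O/S atoms covalently
#' bonded to a hydrogen (bond inferred from the first frame, H within 1.25
#' Angstrom); acceptors are N/O/S atoms other than the donor. Triplets whose
#' frequency over the analyzed frames falls below `freq_cutoff` are dropped.
#'
#' @param traj an `fd_traj` whose topology includes polar hydrogens.
#' @param dist_cutoff H...A distance, Angstrom (default 2.5).
#' @param angle_cutoff D-H...A angle, degrees (default 120).
#' @param freq_cutoff minimum frequency to keep a record (default 0.01).
#' @return data.frame with donor/hydrogen/acceptor atom indices, human
#'   readable ids, and `frequency`; zero rows if nothing passes. An error is
#'   raised when the topology has no hydrogens.
#' @export
hydrogen_bonds <- function(traj, dist_cutoff = 2.5, angle_cutoff = 120,
                           freq_cutoff = 0.01) {
  atoms <- traj$atoms
  h_idx <- which(atoms$element == "H")
  if (length(h_idx) == 0)
    stop_fd("topology contains no hydrogens; hydrogen-bond analysis needs explicit polar H atoms")
  polar <- which(atoms$element %in% c("N", "O", "S"))
  if (length(polar) == 0) stop_fd("no N/O/S atoms in topology")

  xyz0 <- frame_coords(traj, 1)
  # donor of each H: nearest polar atom within covalent range in frame 1
  d0 <- pair_dists(xyz0[h_idx, , drop = FALSE], xyz0[polar, , drop = FALSE])
  don_of_h <- rep(NA_integer_, length(h_idx))
  for (k in seq_along(h_idx)) {
    j <- which.min(d0[k, ])
    if (d0[k, j] < 1.25) don_of_h[k] <- polar[j]
  }
  keep <- !is.na(don_of_h)
  h_idx <- h_idx[keep]; don_of_h <- don_of_h[keep]
  if (length(h_idx) == 0) stop_fd("no polar hydrogens (no H bonded to N/O/S)")

  nf <- n_frames(traj)
  counts <- new.env(hash = TRUE)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    dHA <- pair_dists(xyz[h_idx, , drop = FALSE], xyz[polar, , drop = FALSE])
    hits <- which(dHA < dist_cutoff, arr.ind = TRUE)
    for (r in seq_len(nrow(hits))) {
      hi <- hits[r, 1]; ai <- polar[hits[r, 2]]
      if (ai == don_of_h[hi]) next
      ang <- angle_at_vertex(xyz[don_of_h[hi], ], xyz[h_idx[hi], ], xyz[ai, ])
      if (ang > angle_cutoff) {
        key <- paste(don_of_h[hi], h_idx[hi], ai, sep = "_")
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0)
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), donor_id = character(0),
                      acceptor_id = character(0), frequency = numeric(0)))
  trip <- do.call(rbind, strsplit(keys, "_"))
  freq <- vapply(keys, function(k) counts[[k]], integer(1)) / nf
  atom_id <- function(i)
    sprintf("%s/%s%d/%s", atoms$chain[i], atoms$resname[i], atoms$resid[i],
            atoms$name[i])
  out <- data.frame(donor = as.integer(trip[, 1]),
                    hydrogen = as.integer(trip[, 2]),
                    acceptor = as.integer(trip[, 3]),
                    frequency = unname(freq))
  out$donor_id <- atom_id(out$donor)
  out$acceptor_id <- atom_id(out$acceptor)
  out <- out[out$frequency >= freq_cutoff, ,
             drop = FALSE]
  out <- out[order(-out$frequency, out$donor, out$acceptor), ]
  rownames(out) <- NULL
  out
}
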