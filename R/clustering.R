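# Pairwise Calpha RMSD matrix and GROMOS (Daura) clustering.

#' Pairwise RMSD matrix over trajectory frames
#'
#' Entry (i, j) is the least-squares RMSD after optimal rigid superposition
#' (Kabsch) of frame j onto frame i, computed on the analysis selection
#' itself (default: Calpha atoms).
#'
#' @param traj an `fd_traj`.
#' @param selection integer atom indices into the trajectory's atom table;
#'   NULL selects all atoms named CA (falling back to all atoms if none).
#' @return symmetric n_frames x n_frames matrix (Angstrom), zero diagonal.
#' @export
rmsd_matrix <- function(traj, selection = NULL) {
  nf <- n_frames(traj)
  if (nf < 2) stop_fd("need at least 2 frames")
  if (is.null(selection)) {
    selection <- select_atoms(traj$atoms, name = "CA")
    if (length(selection) == 0) selection <- seq_len(nrow(traj$atoms))
  }
  if (length(selection) < 3) stop_fd("superposition needs >= 3 atoms")
  frames <- lapply(seq_len(nf), function(f)
    frame_coords(traj, f)[selection, , drop = FALSE])
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    for (j in (i + 1):nf) {
      r <- kabsch(frames[[i]], frames[[j]])$rmsd
      m[i, j] <- r
      m[j, i] <- r
    }
  }
  m
}

#' GROMOS (Daura) clustering of an RMSD matrix
#'
#' Iteratively takes the frame with the most neighbours within `cutoff` as a
#' cluster medoid, assigns it and its neighbours to the cluster, removes
#' them, and repeats until no frames remain or `max_clusters` is reached;
#' remaining frames are reported unassigned. Ties on neighbour count are
#' broken toward the lowest frame index.
#'
#' @param m square symmetric distance matrix.
#' @param cutoff neighbour distance threshold, Angstrom (default 6.5).
#' @param max_clusters cap on the number of clusters (default 10).
#' @return object of class `fd_clusters`: list with `cluster` (per-frame id,
#'   NA if unassigned), `medoids` (frame index per cluster, decreasing size),
#'   `sizes`, `cutoff`.
#' @export
gromos_cluster <- function(m, cutoff = 6.5, max_clusters = 10L) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop_fd("distance matrix must be square")
  if (max(abs(m - t(m))) > 1e-8) stop_fd("distance matrix must be symmetric")
  if (cutoff <= 0) stop_fd("cutoff must be > 0")
  n <- nrow(m)
  adj <- m < cutoff
  diag(adj) <- TRUE
  remaining <- rep(TRUE, n)
  cluster <- rep(NA_integer_, n)
  medoids <- integer(0)
  cid <- 0L
  while (any(remaining) && cid < max_clusters) {
    counts <- colSums(adj[remaining, , drop = FALSE])
    counts[!remaining] <- -1L
    med <- which.max(counts)            # which.max takes the first (lowest) tie
    cid <- cid + 1L
    members <- which(remaining & adj[med, ])
    cluster[members] <- cid
    medoids[cid] <- med
    remaining[members] <- FALSE
  }
  sizes <- as.integer(table(factor(cluster, levels = seq_len(cid))))
  # reorder cluster ids by decreasing size (stable: ties keep discovery order)
  ord <- order(-sizes, seq_len(cid))
  remap <- integer(cid)
  remap[ord] <- seq_len(cid)
  structure(list(cluster = remap[cluster], medoids = medoids[ord],
                 sizes = sizes[ord], cutoff = cutoff),
            class = "fd_clusters")
}

#' @export
print.fd_clusters <- function(x, ...) {
  cat(sprintf("GROMOS clustering: %d clusters (sizes %s), %d unassigned, cutoff %.2f A\n",
              length(x$sizes), paste(x$sizes, collapse = ","),
              sum(is.na(x$cluster)), x$cutoff))
  invisible(x)
}

#' Cluster assignment as a tidy table
#' @param cl an `fd_clusters`.
#' @param frame_index optional original frame numbers.
#' @return data.frame with columns frame, cluster, is_medoid.
#' @export
cluster_table <- function(cl, frame_index = NULL) {
  n <- length(cl$cluster)
  fi <- frame_index %||% (seq_len(n) - 1L)
  data.frame(frame = fi, cluster = cl$cluster,
             is_medoid = seq_len(n) %in% cl$medoids)
}
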