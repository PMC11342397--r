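# Heavy-atom contact counting between two selections.

#' Per-frame contact counts between two atom groups
#'
#' Counts atom pairs (a in A, b in B) closer than `cutoff` in each frame.
#' Groups should be disjoint heavy-atom selections; shared atoms would count
#' self-contacts and are rejected.
#'
#' @param traj an `fd_traj`.
#' @param group_a,group_b integer atom indices.
#' @param cutoff Angstrom (default 4.0).
#' @return integer vector, one count per frame.
#' @export
count_contacts <- function(traj, group_a, group_b, cutoff = 4.0) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop_fd("empty contact group")
  if (length(intersect(group_a, group_b)) > 0)
    stop_fd("contact groups must be disjoint")
  vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)
    d <- pair_dists(xyz[group_a, , drop = FALSE], xyz[group_b, , drop = FALSE])
    sum(d < cutoff)
  }, integer(1))
}
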