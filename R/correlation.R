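# Dynamic cross-correlation of Calpha fluctuations and domain-block
# summaries classified as inter-chain vs inter-halves.

#' Dynamic cross-correlation map
#'
#' Frames are least-squares superposed onto the first analyzed frame (on the
#' analysis selection), per-atom deviations from the time-mean position are
#' formed, and the scalar normalized covariance
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` is returned.
#' Zero-variance atoms are reported and their rows/columns masked with NA.
#'
#' @param traj an `fd_traj`.
#' @param selection integer atom indices (default: atoms named CA; all atoms
#'   if none are).
#' @param system optional `fd_system` used to label residues with
#'   (chain label, domain).
#' @return object of class `fd_dccm`: list with `map` (n x n), `labels`
#'   (data.frame chain, resid, label, domain).
#' @export
dccm <- function(traj, selection = NULL, system = NULL) {
  nf <- n_frames(traj)
  if (nf < 2) stop_fd("need at least 2 frames")
  if (is.null(selection)) {
    selection <- select_atoms(traj$atoms, name = "CA")
    if (length(selection) == 0) selection <- seq_len(nrow(traj$atoms))
  }
  ref <- frame_coords(traj, 1)[selection, , drop = FALSE]
  n <- length(selection)
  xs <- array(NA_real_, dim = c(nf, n, 3))
  xs[1, , ] <- ref
  for (f in 2:nf)
    xs[f, , ] <- superpose_onto(ref, frame_coords(traj, f)[selection, , drop = FALSE])
  meanpos <- apply(xs, c(2, 3), mean)
  # covariance of scalar dot products: sum over xyz of per-axis covariances
  cov_ij <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- xs[, , k] - matrix(meanpos[, k], nf, n, byrow = TRUE)
    cov_ij <- cov_ij + crossprod(dk) / nf
  }
  v <- diag(cov_ij)
  zero <- v < 1e-12
  if (any(zero))
    warning(sprintf("%d zero-variance atoms masked in DCCM", sum(zero)))
  denom <- sqrt(outer(v, v))
  map <- cov_ij / denom
  map[zero, ] <- NA_real_
  map[, zero] <- NA_real_
  d <- diag(map)
  d[!zero] <- 1
  diag(map) <- d
  labels <- data.frame(chain = traj$atoms$chain[selection],
                       resid = traj$atoms$resid[selection],
                       label = NA_character_, domain = NA_character_,
                       stringsAsFactors = FALSE)
  if (!is.null(system)) {
    rev_map <- stats::setNames(names(system$chain_map), system$chain_map)
    labels$label <- rev_map[labels$chain]
    dr <- system$domain_ranges
    for (i in seq_len(nrow(dr))) {
      ch <- system$chain_map[[dr$label[i]]]
      hit <- labels$chain == ch & labels$resid >= dr$start[i] &
        labels$resid <= dr$end[i]
      labels$domain[hit] <- dr$domain[i]
    }
  }
  structure(list(map = map, labels = labels), class = "fd_dccm")
}

#' @export
print.fd_dccm <- function(x, ...) {
  cat(sprintf("DCCM: %d x %d, range [%.2f, %.2f]\n", nrow(x$map), ncol(x$map),
              min(x$map, na.rm = TRUE), max(x$map, na.rm = TRUE)))
  invisible(x)
}

#' Domain-block summary of a correlation map
#'
#' Mean correlation for every (chain label + domain) block pair, tagged
#' `intra` (same block), `inter-chain` (different chains within the same
#' antibody half, i.e. LC1/HC1 or LC2/HC2), or `inter-halves` (across
#' halves). Blocks whose mean correlation reaches `threshold` are flagged
#' strong positive.
#'
#' @param dc an `fd_dccm` whose labels carry chain labels and domains (build
#'   it with `system =`).
#' @param threshold flag level (default 0.5).
#' @return data.frame with columns block_a, block_b, mean_correlation,
#'   class, strong.
#' @export
domain_block_summary <- function(dc, threshold = 0.5) {
  lab <- dc$labels
  if (any(is.na(lab$label)) || any(is.na(lab$domain)))
    stop_fd("unlabeled residues: build the DCCM with system = <fd_system>")
  block <- paste(lab$label, lab$domain, sep = ".")
  blocks <- unique(block)
  half <- function(chlab) if (chlab %in% c("LC1", "HC1")) 1L else 2L
  out <- list()
  for (a in seq_along(blocks)) {
    for (b in a:length(blocks)) {
      ia <- which(block == blocks[a]); ib <- which(block == blocks[b])
      sub <- dc$map[ia, ib, drop = FALSE]
      if (a == b) {
        # off-diagonal mean within the block
        vals <- sub[row(sub) != col(sub)]
        cls <- "intra"
      } else {
        vals <- as.vector(sub)
        cha <- sub("\\..*", "", blocks[a]); chb <- sub("\\..*", "", blocks[b])
        cls <- if (cha == chb) "intra-chain"
          else if (half(cha) == half(chb)) "inter-chain" else "inter-halves"
      }
      mc <- mean(vals, na.rm = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        block_a = blocks[a], block_b = blocks[b], mean_correlation = mc,
        class = cls, strong = !is.na(mc) && mc >= threshold,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
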