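# Simplified surface-patch analysis.
#
# This is a deliberately transparent approximation of commercial
# surface-patch tools: exposed residues of the same physico-chemical class
# (hydrophobic / positive / negative) that lie within an adjacency cutoff of
# each other (Cbeta-Cbeta, Calpha for glycine and coarse models) form one
# patch whose area is the sum of member-residue SASA. It reproduces the
# structure of a patch report (per-type patch list and total areas), not any
# proprietary algorithm's numbers.

#' Default residue classification for patch analysis
#' @return named character vector resname -> class.
#' @export
residue_classes_default <- function() {
  c(ALA = "hydrophobic", VAL = "hydrophobic", LEU = "hydrophobic",
    ILE = "hydrophobic", MET = "hydrophobic", PHE = "hydrophobic",
    TRP = "hydrophobic", PRO = "hydrophobic",
    ARG = "positive", LYS = "positive", HIS = "positive",
    ASP = "negative", GLU = "negative")
}

# Reference maximum accessible areas (Angstrom^2) for relative exposure;
# theoretical Gly-X-Gly values (Tien et al. 2013), default for unknowns.
MAX_ASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
             GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
             LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
             SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
MAX_ASA_DEFAULT <- 200

#' Surface patches of one frame
#'
#' @param traj an `fd_traj`.
#' @param frame 1-based frame position (default 1).
#' @param sasa_result an `fd_sasa` over the same trajectory/selection.
#' @param residue_classes named vector resname -> class; residues without a
#'   class are excluded.
#' @param exposure_threshold minimum relative SASA (residue SASA / reference
#'   maximum) to count as exposed (default 0.2).
#' @param adjacency_cutoff Angstrom between residue reference atoms (CB, or
#'   CA when absent) linking residues into one patch (default 8).
#' @return object of class `fd_patches`: data.frame `patches` (patch id,
#'   type, n_residues, area) with member lists in `members`, plus per-type
#'   `totals`.
#' @export
surface_patches <- function(traj, sasa_result, frame = 1L,
                            residue_classes = residue_classes_default(),
                            exposure_threshold = 0.2,
                            adjacency_cutoff = 8.0) {
  res <- sasa_result$residue
  area <- res[[paste0("frame_", frame)]]
  cls <- unname(residue_classes[res$resname])
  maxasa <- MAX_ASA[res$resname]
  maxasa[is.na(maxasa)] <- MAX_ASA_DEFAULT
  exposed <- !is.na(cls) & (area / maxasa) >= exposure_threshold

  # reference atom per residue: CB, else CA, else first atom
  atoms <- traj$atoms
  xyz <- frame_coords(traj, frame)
  ref_xyz <- t(vapply(seq_len(nrow(res)), function(i) {
    cand <- which(atoms$chain == res$chain[i] & atoms$resid == res$resid[i])
    cb <- cand[atoms$name[cand] == "CB"]
    ca <- cand[atoms$name[cand] == "CA"]
    use <- if (length(cb)) cb[1] else if (length(ca)) ca[1] else cand[1]
    xyz[use, ]
  }, numeric(3)))

  patches <- list(); members <- list()
  for (type in unique(stats::na.omit(cls))) {
    cand <- which(exposed & cls == type)
    if (length(cand) == 0) next
    d <- pair_dists(ref_xyz[cand, , drop = FALSE], ref_xyz[cand, , drop = FALSE])
    adj <- d < adjacency_cutoff
    # connected components by BFS
    comp <- rep(NA_integer_, length(cand)); nc <- 0L
    for (s in seq_along(cand)) {
      if (!is.na(comp[s])) next
      nc <- nc + 1L
      queue <- s
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        if (!is.na(comp[v])) next
        comp[v] <- nc
        queue <- c(queue, which(adj[v, ] & is.na(comp)))
      }
    }
    for (k in seq_len(nc)) {
      mem <- cand[comp == k]
      patches[[length(patches) + 1L]] <- data.frame(
        type = type, n_residues = length(mem), area = sum(area[mem]),
        stringsAsFactors = FALSE)
      members[[length(members) + 1L]] <-
        res[mem, c("chain", "resid", "resname")]
    }
  }
  ptab <- if (length(patches)) {
    out <- do.call(rbind, patches)
    out$patch <- seq_len(nrow(out))
    out[, c("patch", "type", "n_residues", "area")]
  } else {
    data.frame(patch = integer(0), type = character(0),
               n_residues = integer(0), area = numeric(0))
  }
  totals <- if (nrow(ptab)) {
    stats::aggregate(area ~ type, data = ptab, FUN = sum)
  } else {
    data.frame(type = character(0), area = numeric(0))
  }
  structure(list(patches = ptab, members = members, totals = totals),
            class = "fd_patches")
}

#' @export
print.fd_patches <- function(x, ...) {
  cat(sprintf("PatchSet: %d patches\n", nrow(x$patches)))
  if (nrow(x$totals)) print(x$totals)
  invisible(x)
}
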