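# DSSP-style secondary-structure assignment from backbone geometry.
#
# Hydrogen bonds follow the Kabsch-Sander electrostatic model:
#   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  [kcal/mol]
# with a bond when E < -0.5 kcal/mol. HB(i, j) denotes a bond from the C=O
# of residue i to the N-H of residue j; covalent neighbours (|i-j| < 2
# within a chain) are excluded. Patterns: two consecutive n-turns make a
# helix (n = 4 -> H, 3 -> G, 5 -> I), mutual or offset bond pairs make
# bridges (isolated -> B, laddered -> E), single turns -> T, and a Calpha
# kink above 70 degrees -> S. Assignment priority: H, E, B, G, I, T, S.

DSSP_Q <- 0.084 * 332
DSSP_EMAX <- -0.5

# Extract per-residue backbone coordinates for one frame.
backbone_table <- function(atoms) {
  key <- paste(atoms$chain, atoms$resid, sep = "_")
  res_key <- unique(key)
  res <- data.frame(chain = sub("_.*", "", res_key),
                    resid = as.integer(sub(".*_", "", res_key)),
                    stringsAsFactors = FALSE)
  res <- res[order(res$chain, res$resid), ]
  idx_of <- function(name) {
    m <- match(paste(res$chain, res$resid, name, sep = "_"),
               paste(atoms$chain, atoms$resid, atoms$name, sep = "_"))
    m
  }
  list(res = res, N = idx_of("N"), CA = idx_of("CA"), C = idx_of("C"),
       O = idx_of("O"), H = idx_of("H"))
}

#' DSSP-style secondary structure over a trajectory
#'
#' @param traj an `fd_traj` whose topology provides backbone N, CA, C, O per
#'   residue (amide H is used when present, else inferred from the previous
#'   residue's C=O direction).
#' @param selection optional atom indices restricting the analyzed residues.
#' @return object of class `fd_ss`: list with `codes` (residues x frames
#'   character matrix of 8-state codes), `residues` (chain/resid table),
#'   `frequency` (per-residue percent of frames in each code), and
#'   `categories` (percent in helix/extended/turn/bend/none).
#' @export
secondary_structure <- function(traj, selection = NULL) {
  atoms <- traj$atoms
  if (!is.null(selection)) atoms <- atoms[selection, , drop = FALSE]
  bb <- backbone_table(atoms)
  nres <- nrow(bb$res)
  incomplete <- is.na(bb$N) | is.na(bb$CA) | is.na(bb$C) | is.na(bb$O)
  if (mean(incomplete) > 0.10)
    stop_fd("backbone atoms missing for %d/%d residues (> 10%%)",
            sum(incomplete), nres)
  sel_rows <- if (is.null(selection)) seq_len(nrow(traj$atoms)) else selection
  nf <- n_frames(traj)
  codes <- matrix("-", nres, nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)[sel_rows, , drop = FALSE]
    codes[, f] <- dssp_frame(xyz, bb, incomplete)
  }
  lv <- c("H", "G", "I", "E", "B", "T", "S", "-")
  freq <- t(apply(codes, 1, function(r) table(factor(r, levels = lv)) / nf)) * 100
  colnames(freq) <- lv
  cat_map <- c(H = "helix", G = "helix", I = "helix", E = "extended",
               B = "extended", T = "turn", S = "bend", "-" = "none")
  cats <- sapply(c("helix", "extended", "turn", "bend", "none"), function(cc)
    rowSums(freq[, names(cat_map)[cat_map == cc], drop = FALSE]))
  structure(list(codes = codes, residues = bb$res, frequency = freq,
                 categories = cats), class = "fd_ss")
}

dssp_frame <- function(xyz, bb, incomplete) {
  nres <- nrow(bb$res)
  N <- xyz[bb$N, , drop = FALSE]
  CA <- xyz[bb$CA, , drop = FALSE]
  C <- xyz[bb$C, , drop = FALSE]
  O <- xyz[bb$O, , drop = FALSE]
  chain <- bb$res$chain
  # amide H: explicit atom if present, else inferred along prev C=O
  H <- matrix(NA_real_, nres, 3)
  for (i in seq_len(nres)) {
    if (!is.na(bb$H[i])) {
      H[i, ] <- xyz[bb$H[i], ]
    } else if (i > 1 && chain[i] == chain[i - 1] &&
               !incomplete[i] && !incomplete[i - 1]) {
      H[i, ] <- N[i, ] + unitv(C[i - 1, ] - O[i - 1, ])
    }
  }
  # candidate pairs: CA within 9 A
  hb <- matrix(FALSE, nres, nres)   # hb[i, j]: CO(i) ... HN(j)
  for (i in seq_len(nres)) {
    if (incomplete[i]) next
    for (j in seq_len(nres)) {
      if (incomplete[j] || i == j) next
      if (chain[i] == chain[j] && abs(i - j) < 2) next
      if (any(is.na(H[j, ]))) next
      if (vnorm(CA[i, ] - CA[j, ]) > 9) next
      r_on <- vnorm(O[i, ] - N[j, ])
      r_ch <- vnorm(C[i, ] - H[j, ])
      r_oh <- vnorm(O[i, ] - H[j, ])
      r_cn <- vnorm(C[i, ] - N[j, ])
      if (min(r_on, r_ch, r_oh, r_cn) < 0.5) next
      e <- DSSP_Q * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
      hb[i, j] <- e < DSSP_EMAX
    }
  }
  same_chain_span <- function(i, j) {
    all(chain[i:j] == chain[i])
  }
  turn <- function(i, n) {
    i >= 1 && i + n <= nres && same_chain_span(i, i + n) && hb[i, i + n]
  }
  code <- rep("-", nres)
  setc <- function(idx, ch) {
    # priority: keep stronger codes already assigned
    pr <- c(H = 1, E = 2, B = 3, G = 4, I = 5, T = 6, S = 7, "-" = 8)
    for (k in idx) if (pr[[ch]] < pr[[code[k]]]) code[k] <<- ch
  }
  # helices: two consecutive n-turns
  for (n in c(4, 3, 5)) {
    ch <- c(`3` = "G", `4` = "H", `5` = "I")[[as.character(n)]]
    if (nres - n - 1 < 1) next
    for (i in seq_len(nres - n - 1)) {
      if (turn(i, n) && turn(i + 1, n)) setc((i + 1):(i + n), ch)
    }
  }
  # bridges
  bridged <- rep(FALSE, nres)
  for (i in seq_len(nres)) {
    for (j in seq_len(nres)) {
      if (i == j) next
      if (chain[i] == chain[j] && abs(i - j) < 3) next
      par <- (i > 1 && i < nres && hb[i - 1, j] && hb[j, i + 1]) ||
             (j > 1 && j < nres && hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) ||
              (i > 1 && i < nres && j > 1 && j < nres &&
               hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti) bridged[i] <- TRUE
    }
  }
  for (i in which(bridged)) {
    ladder <- (i > 1 && bridged[i - 1] && chain[i - 1] == chain[i]) ||
              (i < nres && bridged[i + 1] && chain[i + 1] == chain[i])
    setc(i, if (ladder) "E" else "B")
  }
  # turns
  for (n in 3:5) {
    for (i in seq_len(nres)) {
      if (turn(i, n)) setc((i + 1):(i + n - 1), "T")
    }
  }
  # bend: Calpha kink > 70 degrees
  for (i in seq_len(nres)) {
    if (i < 3 || i + 2 > nres) next
    if (!same_chain_span(i - 2, i + 2)) next
    if (any(is.na(CA[(i - 2):(i + 2), 1]))) next
    u <- CA[i, ] - CA[i - 2, ]; w <- CA[i + 2, ] - CA[i, ]
    if (vnorm(u) < 1e-6 || vnorm(w) < 1e-6) next
    ang <- deg(acos(pmin(pmax(sum(u * w) / (vnorm(u) * vnorm(w)), -1), 1)))
    if (ang > 70) setc(i, "S")
  }
  code
}
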