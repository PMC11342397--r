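# Accelerated-MD support: boost-parameter arithmetic, Maclaurin reweighting,
# free-energy surface estimation, and minimum-energy frame extraction.

#' Accelerated-MD boost parameters from classical-MD averages
#'
#' Standard dual-boost recipe: the potential-energy threshold is the average
#' potential energy plus `c_p` kcal/mol per atom, with `alpha_p` equal to the
#' same per-atom term; the dihedral threshold is the average dihedral energy
#' plus `c_d` kcal/mol per residue, with `alpha_d` that term divided by
#' `alpha_d_divisor`. The coefficients are configurable.
#'
#' @param avg_eptot average potential energy from classical MD, kcal/mol.
#' @param avg_dihed average dihedral energy, kcal/mol.
#' @param n_atoms,n_res system size.
#' @param c_p kcal/mol per atom (default 0.2).
#' @param c_d kcal/mol per residue (default 3.5).
#' @param alpha_d_divisor default 5.
#' @return list of class `fd_amd_params` with `ethresh_p`, `alpha_p`,
#'   `ethresh_d`, `alpha_d` and the coefficients used.
#' @export
amd_parameters <- function(avg_eptot, avg_dihed, n_atoms, n_res,
                           c_p = 0.2, c_d = 3.5, alpha_d_divisor = 5) {
  if (n_atoms <= 0 || n_res <= 0) stop_fd("n_atoms and n_res must be positive")
  alpha_p <- c_p * n_atoms
  alpha_d <- c_d * n_res / alpha_d_divisor
  if (alpha_p <= 0 || alpha_d <= 0)
    stop_fd("alpha parameters must be > 0 (check c_p/c_d)")
  structure(list(ethresh_p = avg_eptot + c_p * n_atoms, alpha_p = alpha_p,
                 ethresh_d = avg_dihed + c_d * n_res, alpha_d = alpha_d,
                 coeffs = list(c_p = c_p, c_d = c_d,
                               alpha_d_divisor = alpha_d_divisor)),
            class = "fd_amd_params")
}

#' Maclaurin-series reweighting factors
#'
#' Per-frame weight `sum_{k=0}^{order} (beta dV)^k / k!`, the truncated
#' Maclaurin expansion of `exp(beta dV)` used to reweight boosted ensembles
#' (Miao-style). `mode = "exp"` gives the exact exponential for validation.
#'
#' @param boost an `fd_boost` or numeric vector of boost energies (kcal/mol).
#' @param temperature Kelvin (default 300).
#' @param order Maclaurin truncation order (default 10).
#' @param mode "maclaurin" (default) or "exp".
#' @return numeric vector of per-frame weights.
#' @export
maclaurin_weights <- function(boost, temperature = 300, order = 10L,
                              mode = c("maclaurin", "exp")) {
  mode <- match.arg(mode)
  dv <- if (inherits(boost, "fd_boost")) boost$delta_v else as.numeric(boost)
  if (temperature <= 0) stop_fd("temperature must be positive")
  if (order < 0) stop_fd("order must be >= 0")
  x <- dv / (KB_KCAL * temperature)
  if (mode == "exp") return(exp(x))
  w <- rep(1, length(x))
  term <- rep(1, length(x))
  for (k in seq_len(order)) {
    term <- term * x / k
    w <- w + term
  }
  w
}

#' Reweighted 2-D free-energy surface over (theta1, theta2)
#'
#' Weighted 2-D histogram of the angle samples, normalized over occupied
#' bins; `PMF = -kB T ln p`, shifted so the minimum over occupied bins is
#' zero. Empty bins are masked (PMF = NA).
#'
#' @param theta1,theta2 angle samples, degrees.
#' @param weights per-frame weights (unit weights give the unweighted FES).
#' @param bins number of bins per axis (default 60) or a list of two edge
#'   vectors.
#' @param range length-2 numeric: common axis limits (default c(0, 180));
#'   ignored when explicit edges are supplied.
#' @param temperature Kelvin (default 300).
#' @return object of class `fd_fes`: list with `edges1`, `edges2`, `counts`,
#'   `wsum`, `prob`, `pmf` (matrices), `occupied` mask, `temperature`.
#' @export
reweighted_fes <- function(theta1, theta2, weights = NULL, bins = 60L,
                           range = c(0, 180), temperature = 300) {
  if (any(is.na(theta1)) || any(is.na(theta2)))
    stop_fd("NaN/NA angle samples")
  n <- length(theta1)
  stopifnot(length(theta2) == n)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop_fd("weights not aligned with samples")
  if (all(weights == 0)) stop_fd("all-zero weights")
  if (is.list(bins)) {
    e1 <- bins[[1]]; e2 <- bins[[2]]
  } else {
    if (bins < 2) stop_fd("need at least 2 bins per axis")
    e1 <- seq(range[1], range[2], length.out = bins + 1L)
    e2 <- e1
  }
  b1 <- bin_index(theta1, e1)
  b2 <- bin_index(theta2, e2)
  ok <- !is.na(b1) & !is.na(b2)
  n1 <- length(e1) - 1L; n2 <- length(e2) - 1L
  counts <- matrix(0, n1, n2)
  wsum <- matrix(0, n1, n2)
  for (i in which(ok)) {
    counts[b1[i], b2[i]] <- counts[b1[i], b2[i]] + 1
    wsum[b1[i], b2[i]] <- wsum[b1[i], b2[i]] + weights[i]
  }
  occupied <- counts > 0
  prob <- wsum / sum(wsum)
  pmf <- matrix(NA_real_, n1, n2)
  kt <- KB_KCAL * temperature
  pmf[occupied] <- -kt * log(prob[occupied])
  pmf[occupied] <- pmf[occupied] - min(pmf[occupied])
  structure(list(edges1 = e1, edges2 = e2, counts = counts, wsum = wsum,
                 prob = prob, pmf = pmf, occupied = occupied,
                 temperature = temperature),
            class = "fd_fes")
}

# 1-based bin index with right-closed last bin; NA outside the edges.
bin_index <- function(x, edges) {
  b <- findInterval(x, edges, rightmost.closed = TRUE)
  b[b < 1 | b > length(edges) - 1L] <- NA_integer_
  b
}

#' @export
print.fd_fes <- function(x, ...) {
  cat(sprintf("FESGrid: %d x %d bins, %d occupied, PMF range [0, %.2f] kcal/mol\n",
              nrow(x$pmf), ncol(x$pmf), sum(x$occupied),
              max(x$pmf, na.rm = TRUE)))
  invisible(x)
}

#' Write a free-energy surface as a long-format CSV
#'
#' Columns: theta1_bin, theta2_bin (bin centres), count, prob, pmf.
#' @param fes an `fd_fes`.
#' @param path output path.
#' @export
write_fes_csv <- function(fes, path) {
  c1 <- (fes$edges1[-1] + fes$edges1[-length(fes$edges1)]) / 2
  c2 <- (fes$edges2[-1] + fes$edges2[-length(fes$edges2)]) / 2
  df <- expand.grid(theta1_bin = c1, theta2_bin = c2)
  df$count <- as.vector(fes$counts)
  df$prob <- as.vector(fes$prob)
  df$pmf <- as.vector(fes$pmf)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Frames inside the minimum-energy region of a free-energy surface
#'
#' Selects the frames whose (theta1, theta2) fall in an occupied bin with
#' PMF below the threshold (default 0.5 kcal/mol), preserving order.
#'
#' @param fes an `fd_fes`.
#' @param theta1,theta2 the same angle samples the surface was built from.
#' @param pmf_threshold kcal/mol (default 0.5, must be > 0).
#' @return 1-based integer indices into the sample vectors.
#' @export
minimum_energy_frames <- function(fes, theta1, theta2, pmf_threshold = 0.5) {
  if (pmf_threshold <= 0) stop_fd("pmf_threshold must be > 0")
  b1 <- bin_index(theta1, fes$edges1)
  b2 <- bin_index(theta2, fes$edges2)
  ok <- !is.na(b1) & !is.na(b2)
  sel <- logical(length(theta1))
  idx <- cbind(b1[ok], b2[ok])
  v <- fes$pmf[idx]
  sel[ok] <- !is.na(v) & v < pmf_threshold
  which(sel)
}
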