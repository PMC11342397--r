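# Shared numerical helpers and physical constants.

#' Boltzmann constant in kcal/(mol K)
#' @keywords internal
KB_KCAL <- 0.0019872041

deg <- function(x) x * 180 / pi
rad <- function(x) x * pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Optimal superposition (Kabsch) of two coordinate sets
#'
#' Returns the minimum root-mean-square deviation between two conformations of
#' the same atom set after optimal rigid-body superposition, together with the
#' rotation that achieves it.
#'
#' @param p,q numeric matrices (n x 3), matched row-for-row.
#' @return list with `rmsd` (Angstrom), `rotation` (3 x 3, maps centred `q`
#'   onto centred `p`), and the two centroids.
#' @export
kabsch <- function(p, q) {
  stopifnot(is.matrix(p), is.matrix(q), ncol(p) == 3, ncol(q) == 3,
            nrow(p) == nrow(q))
  n <- nrow(p)
  if (n < 3) stop("superposition needs at least 3 atoms")
  cp <- colMeans(p)
  cq <- colMeans(q)
  p0 <- sweep(p, 2, cp)
  q0 <- sweep(q, 2, cq)
  h <- crossprod(q0, p0)          # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  s <- c(1, 1, d)
  rot <- sv$v %*% diag(s) %*% t(sv$u)
  # rmsd from the explicit residuals: numerically stable near zero, where the
  # inner-product shortcut loses ~7 digits to cancellation
  resid <- p0 - q0 %*% t(rot)
  list(rmsd = sqrt(sum(resid^2) / n), rotation = rot,
       center_p = cp, center_q = cq)
}

# Apply the Kabsch fit: returns q superposed onto p (n x 3).
superpose_onto <- function(p, q) {
  k <- kabsch(p, q)
  sweep(sweep(q, 2, k$center_q) %*% t(k$rotation), 2, k$center_p, `+`)
}

# Map angles (degrees) to the half-open interval (-180, 180].
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# Make an angle series (degrees) continuous across the +-180 seam.
unwrap_deg <- function(phi) {
  if (length(phi) < 2) return(phi)
  d <- diff(phi)
  corr <- cumsum(ifelse(d > 180, -360, ifelse(d < -180, 360, 0)))
  c(phi[1], phi[-1] + corr)
}

stop_fd <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
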