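# CHARMM/NAMD-style DCD binary trajectory reader and writer.
#
# DCD is a Fortran unformatted stream: every logical record is framed by
# 4-byte length markers. The header carries the 'CORD' magic plus a 20-slot
# integer control block (frame count, stride, unit-cell flag in slot 11,
# version in slot 20). Coordinates are single-precision, one record per
# Cartesian component per frame. Files are read and written in native byte
# order.

read_fort_record <- function(con, what, size) {
  n1 <- readBin(con, "integer", 1, size = 4)
  if (length(n1) == 0) return(NULL)
  nitems <- n1 / size
  dat <- readBin(con, what, nitems, size = size)
  n2 <- readBin(con, "integer", 1, size = 4)
  if (length(n2) == 0 || n2 != n1) stop_fd("corrupt DCD record framing")
  dat
}

write_fort_record <- function(con, dat, size) {
  nb <- length(dat) * size
  writeBin(as.integer(nb), con, size = 4)
  if (is.raw(dat)) writeBin(dat, con) else writeBin(dat, con, size = size)
  writeBin(as.integer(nb), con, size = 4)
}

#' Read a DCD trajectory
#'
#' @param path DCD file path.
#' @return list with `coords` (n_frames x n_atoms x 3, Angstrom) and
#'   `n_atoms`, `n_frames`.
#' @export
read_dcd <- function(path) {
  if (!file.exists(path)) stop_fd("DCD file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))

  n1 <- readBin(con, "integer", 1, size = 4)
  if (length(n1) == 0 || n1 != 84) stop_fd("not a DCD file (bad header length): %s", path)
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "CORD") stop_fd("not a DCD file (magic '%s'): %s", magic, path)
  icntrl_raw <- readBin(con, "raw", 80)
  n2 <- readBin(con, "integer", 1, size = 4)
  if (n2 != 84) stop_fd("corrupt DCD header framing")
  icntrl <- readBin(icntrl_raw, "integer", 20, size = 4)
  has_cell <- icntrl[11] != 0

  invisible(read_fort_record(con, "raw", 1))   # title block
  natom <- read_fort_record(con, "integer", 4)
  if (length(natom) != 1) stop_fd("corrupt DCD natom record")
  natom <- natom[1]

  frames <- list()
  repeat {
    if (has_cell) {
      cell <- read_fort_record(con, "double", 8)
      if (is.null(cell)) break
    }
    x <- read_fort_record(con, "double", 4)
    if (is.null(x)) break
    y <- read_fort_record(con, "double", 4)
    z <- read_fort_record(con, "double", 4)
    if (length(x) != natom || length(y) != natom || length(z) != natom)
      stop_fd("DCD frame atom count mismatch (expected %d)", natom)
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
  }
  nf <- length(frames)
  coords <- array(NA_real_, dim = c(nf, natom, 3))
  for (f in seq_len(nf)) coords[f, , ] <- frames[[f]]
  list(coords = coords, n_atoms = natom, n_frames = nf)
}

# readBin on a connection handles size=4 doubles (float32) natively; when
# reading from a raw vector we only ever pull integers, so no shim is needed.

#' Write a DCD trajectory
#'
#' Coordinates are stored as single precision, so a write/read round trip
#' preserves values to float32 resolution (~1e-6 relative).
#'
#' @param coords n_frames x n_atoms x 3 array (Angstrom).
#' @param path output path.
#' @export
write_dcd <- function(coords, path) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  nf <- dim(coords)[1]
  na <- dim(coords)[2]
  con <- file(path, "wb")
  on.exit(close(con))

  icntrl <- integer(20)
  icntrl[1] <- nf      # frames in file
  icntrl[2] <- 1L      # first step
  icntrl[3] <- 1L      # save stride
  icntrl[4] <- nf      # total steps
  icntrl[20] <- 24L    # CHARMM version stamp
  writeBin(84L, con, size = 4)
  writeBin(charToRaw("CORD"), con)
  writeBin(icntrl, con, size = 4)
  writeBin(84L, con, size = 4)

  title <- sprintf("%-80s", "Created by fabdyn")
  writeBin(84L, con, size = 4)
  writeBin(1L, con, size = 4)
  writeBin(charToRaw(title), con)
  writeBin(84L, con, size = 4)

  write_fort_record(con, na, 4L)

  for (f in seq_len(nf)) {
    for (k in 1:3) write_fort_record(con, as.double(coords[f, , k]), 4L)
  }
  invisible(path)
}
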