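# Minimal fixed-column PDB reader/writer.
#
# The analysis environment ships no R package for molecular topologies, so the
# package carries its own parser for the small subset of the format it needs:
# ATOM/HETATM records and MODEL/ENDMDL frame delimiters. Columns follow the
# wwPDB v3.3 fixed layout; coordinates are Angstrom.

#' Read a PDB file into a topology table
#'
#' Parses ATOM and HETATM records. If the file contains several MODEL blocks,
#' the topology is taken from the first model and the remaining models are
#' returned as extra coordinate frames.
#'
#' @param path path to a PDB file.
#' @return object of class `fd_topology`: a data.frame with columns
#'   `serial`, `name`, `resname`, `chain`, `resid`, `x`, `y`, `z`, `element`,
#'   plus an attribute `frames` (n_frames x n_atoms x 3 array).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop_fd("PDB file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  is_model_end <- startsWith(lines, "ENDMDL")
  if (!any(is_atom)) stop_fd("no ATOM/HETATM records in %s", path)

  # split atom lines into models
  model_id <- cumsum(is_model_end)
  atom_lines <- lines[is_atom]
  atom_model <- model_id[is_atom]
  first <- atom_lines[atom_model == atom_model[1]]

  parse_block <- function(ln) {
    data.frame(
      serial  = as.integer(substr(ln, 7, 11)),
      name    = trimws(substr(ln, 13, 16)),
      resname = trimws(substr(ln, 18, 20)),
      chain   = trimws(substr(ln, 22, 22)),
      resid   = as.integer(substr(ln, 23, 26)),
      x = as.numeric(substr(ln, 31, 38)),
      y = as.numeric(substr(ln, 39, 46)),
      z = as.numeric(substr(ln, 47, 54)),
      element = trimws(substr(ln, 77, 78)),
      stringsAsFactors = FALSE
    )
  }
  top <- parse_block(first)
  # derive element from atom name when column 77-78 is absent
  miss <- top$element == "" | is.na(top$element)
  if (any(miss)) top$element[miss] <- guess_element(top$name[miss])

  models <- split(atom_lines, atom_model)
  na <- nrow(top)
  frames <- array(NA_real_, dim = c(length(models), na, 3))
  for (m in seq_along(models)) {
    b <- parse_block(models[[m]])
    if (nrow(b) != na)
      stop_fd("model %d has %d atoms, expected %d", m, nrow(b), na)
    frames[m, , ] <- as.matrix(b[, c("x", "y", "z")])
  }
  attr(top, "frames") <- frames
  class(top) <- c("fd_topology", "data.frame")
  top
}

guess_element <- function(name) {
  # strip digits/quotes, take the leading letter(s); two-letter elements that
  # occur in protein/glycan systems are not expected here beyond these
  lead <- toupper(sub("^[0-9']*", "", name))
  el <- substr(lead, 1, 1)
  two <- substr(lead, 1, 2)
  el[two %in% c("CL", "NA", "MG", "ZN", "FE", "BR")] <-
    two[two %in% c("CL", "NA", "MG", "ZN", "FE", "BR")]
  el
}

#' Write a topology (and optional trajectory frames) as a PDB file
#'
#' @param top an `fd_topology` data.frame.
#' @param path output path.
#' @param coords optional n_frames x n_atoms x 3 array; defaults to the
#'   topology's own coordinates (one model).
#' @export
write_pdb <- function(top, path, coords = NULL) {
  if (is.null(coords)) {
    coords <- array(as.matrix(top[, c("x", "y", "z")]),
                    dim = c(1, nrow(top), 3))
  }
  nf <- dim(coords)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    # PDB atom-name column convention: names <4 chars start in column 14
    nm <- ifelse(nchar(top$name) < 4, sprintf(" %-3s", top$name),
                 sprintf("%-4s", top$name))
    writeLines(sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      top$serial %% 100000, nm, top$resname, top$chain, top$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], top$element), con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
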