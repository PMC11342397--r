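# Data model and file loaders: trajectories, chain/domain annotations, and
# accelerated-MD boost-energy logs.
#
# Conventions used throughout the package: frame indexing is 0-based, lengths
# are Angstrom, energies kcal/mol, angles degrees. Residue numbering follows
# the input topology verbatim; antibody-specific numbers (Asn299, Cys228,
# Val34) live in the annotation config, never in code.

# ---------------------------------------------------------------- trajectory

#' Construct a TrajectorySlice
#'
#' @param coords n_frames x n_atoms x 3 array, Angstrom.
#' @param atoms topology table for exactly the atoms in `coords`.
#' @param frame_index 0-based original frame numbers (strictly increasing).
#' @param box optional per-frame periodic box (n_frames x 6) or NULL.
#' @return object of class `fd_traj`.
#' @export
trajectory_slice <- function(coords, atoms, frame_index = NULL, box = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[2] != nrow(atoms))
    stop_fd("coords have %d atoms but atom table has %d rows",
            dim(coords)[2], nrow(atoms))
  nf <- dim(coords)[1]
  if (is.null(frame_index)) frame_index <- seq_len(nf) - 1L
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != nf)
    stop_fd("frame_index length %d != %d frames", length(frame_index), nf)
  if (nf > 1 && any(diff(frame_index) <= 0))
    stop_fd("frame_index must be strictly increasing")
  structure(list(coords = coords, atoms = atoms,
                 frame_index = frame_index, box = box),
            class = "fd_traj")
}

#' @export
print.fd_traj <- function(x, ...) {
  cat(sprintf("TrajectorySlice: %d frames x %d atoms\n",
              n_frames(x), dim(x$coords)[2]))
  invisible(x)
}

#' Number of frames in a trajectory slice
#' @param traj an `fd_traj`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Coordinates of one frame
#' @param traj an `fd_traj`.
#' @param i frame position (1-based within the slice).
#' @return n_atoms x 3 matrix.
#' @export
frame_coords <- function(traj, i) {
  m <- traj$coords[i, , , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, ncol = 3)
  m
}

#' Restrict a trajectory slice to a subset of frames
#' @param traj an `fd_traj`.
#' @param idx 1-based frame positions to keep.
#' @export
subset_frames <- function(traj, idx) {
  trajectory_slice(traj$coords[idx, , , drop = FALSE], traj$atoms,
                   traj$frame_index[idx],
                   if (!is.null(traj$box)) traj$box[idx, , drop = FALSE])
}

#' Load a trajectory into a TrajectorySlice
#'
#' Reads a PDB topology and one or more trajectory files, concatenates frames
#' in file order, applies a uniform stride, and restricts to an atom
#' selection. Supported trajectory formats are DCD and multi-model PDB; XTC
#' and AMBER NetCDF require compression/HDF libraries not available to this
#' package and are rejected with a clear error.
#'
#' @param topology_path PDB file defining the atoms.
#' @param trajectory_paths character vector of DCD (or multi-model PDB) files;
#'   NULL uses the topology's own models as frames.
#' @param selection optional integer atom indices (as from [select_atoms()]);
#'   NULL keeps all atoms.
#' @param stride keep every `stride`-th frame (default 1).
#' @return an `fd_traj`; `frame_index` refers to the 0-based concatenated
#'   frame numbering before striding.
#' @export
load_trajectory <- function(topology_path, trajectory_paths = NULL,
                            selection = NULL, stride = 1L) {
  top <- read_pdb(topology_path)
  stride <- as.integer(stride)
  if (stride < 1) stop_fd("stride must be >= 1")

  if (is.null(trajectory_paths)) {
    coords <- attr(top, "frames")
  } else {
    blocks <- lapply(trajectory_paths, function(p) {
      ext <- tolower(tools::file_ext(p))
      if (ext %in% c("xtc", "nc", "ncdf", "netcdf"))
        stop_fd("trajectory format '%s' is not supported (use DCD or multi-model PDB)", ext)
      if (ext == "dcd") {
        d <- read_dcd(p)
        if (d$n_atoms != nrow(top))
          stop_fd("%s has %d atoms; topology has %d", p, d$n_atoms, nrow(top))
        d$coords
      } else {
        t2 <- read_pdb(p)
        fr <- attr(t2, "frames")
        if (dim(fr)[2] != nrow(top))
          stop_fd("%s has %d atoms; topology has %d", p, dim(fr)[2], nrow(top))
        fr
      }
    })
    nf_tot <- sum(vapply(blocks, function(b) dim(b)[1], 1L))
    coords <- array(NA_real_, dim = c(nf_tot, nrow(top), 3))
    at <- 1L
    for (b in blocks) {
      nb <- dim(b)[1]
      coords[at:(at + nb - 1L), , ] <- b
      at <- at + nb
    }
  }
  nf <- dim(coords)[1]
  keep <- seq(1L, nf, by = stride)
  sel <- selection %||% seq_len(nrow(top))
  if (length(sel) == 0) stop_fd("empty atom selection")
  atoms <- top[sel, , drop = FALSE]
  attr(atoms, "frames") <- NULL
  class(atoms) <- "data.frame"
  trajectory_slice(coords[keep, sel, , drop = FALSE], atoms,
                   frame_index = keep - 1L)
}

# ---------------------------------------------------------------- annotation

#' Construct an AnnotatedSystem
#'
#' Carries the chain identities (LC1/LC2/HC1/HC2), domain residue intervals,
#' glycan selections, named residue sets (hinge, receptor-binding sites), and
#' descriptor anchor atoms for one antibody system.
#'
#' @param chain_map named character vector: label in
#'   {LC1, LC2, HC1, HC2} -> chain id in the topology.
#' @param domain_ranges data.frame with columns `label`, `domain`, `start`,
#'   `end` (inclusive residue interval on the labelled chain).
#' @param glycans named list; each element a list with `chain` (topology chain
#'   id) and optional `resid` (residue numbers).
#' @param residue_sets named list; each element a data.frame with columns
#'   `label` (chain label) and `resid`.
#' @param anchors named list; each element a list with `label` (chain label)
#'   or `chain` (explicit chain id), `resid`, and `atom` name.
#' @return object of class `fd_system`.
#' @export
annotated_system <- function(chain_map, domain_ranges,
                             glycans = list(), residue_sets = list(),
                             anchors = list()) {
  need <- c("LC1", "LC2", "HC1", "HC2")
  missing_lab <- setdiff(need, names(chain_map))
  if (length(missing_lab) > 0)
    stop_fd("annotation is missing chain label(s): %s",
            paste(missing_lab, collapse = ", "))
  if (anyDuplicated(chain_map[need]))
    stop_fd("the four chain labels must map to distinct chains")
  dr <- as.data.frame(domain_ranges)
  stopifnot(all(c("label", "domain", "start", "end") %in% names(dr)))
  if (any(dr$end < dr$start))
    stop_fd("domain interval with end < start")
  # domains required downstream
  for (dom in c("VH", "VL", "CH2")) {
    if (!dom %in% dr$domain)
      stop_fd("annotation must declare domain '%s'", dom)
  }
  # overlapping intervals within one chain label are configuration errors
  for (lab in unique(dr$label)) {
    sub <- dr[dr$label == lab, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)]))
      stop_fd("overlapping domain intervals on chain label %s", lab)
  }
  structure(list(schema = "fabdyn-annotation/1",
                 chain_map = chain_map, domain_ranges = dr,
                 glycans = glycans, residue_sets = residue_sets,
                 anchors = anchors),
            class = "fd_system")
}

#' @export
print.fd_system <- function(x, ...) {
  cat("AnnotatedSystem\n  chains:",
      paste(sprintf("%s=%s", names(x$chain_map), x$chain_map), collapse = " "),
      sprintf("\n  %d domain intervals, %d glycans, %d residue sets, %d anchors\n",
              nrow(x$domain_ranges), length(x$glycans),
              length(x$residue_sets), length(x$anchors)))
  invisible(x)
}

#' Load an annotation config (JSON)
#'
#' The config is a versioned, human-editable JSON mapping (schema
#' `fabdyn-annotation/1`) with blocks `chains`, `domains`, `glycans`,
#' `residue_sets`, `anchors`. See [annotated_system()] for semantics.
#'
#' @param path JSON config file.
#' @return an `fd_system`.
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) stop_fd("annotation config not found: %s", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  chains <- unlist(cfg$chains)
  doms <- cfg$domains %||% list()
  rows <- list()
  for (lab in names(doms)) {
    for (dom in names(doms[[lab]])) {
      iv <- as.integer(unlist(doms[[lab]][[dom]]))
      rows[[length(rows) + 1L]] <-
        data.frame(label = lab, domain = dom, start = iv[1], end = iv[2])
    }
  }
  dr <- do.call(rbind, rows)
  glycans <- lapply(cfg$glycans %||% list(), function(g) {
    list(chain = g$chain, resid = if (!is.null(g$resid)) as.integer(unlist(g$resid)))
  })
  rsets <- lapply(cfg$residue_sets %||% list(), function(entries) {
    do.call(rbind, lapply(entries, function(e)
      data.frame(label = e$chain, resid = as.integer(unlist(e$resid)))))
  })
  anchors <- lapply(cfg$anchors %||% list(), function(a) {
    list(label = a$chain, resid = as.integer(a$resid), atom = a$atom)
  })
  annotated_system(chains, dr, glycans, rsets, anchors)
}

#' Write an annotation config (JSON)
#'
#' Inverse of [load_annotation()]; a load/write/load round trip yields an
#' identical system.
#'
#' @param system an `fd_system`.
#' @param path output path.
#' @export
write_annotation <- function(system, path) {
  doms <- list()
  for (i in seq_len(nrow(system$domain_ranges))) {
    r <- system$domain_ranges[i, ]
    doms[[r$label]][[r$domain]] <- c(r$start, r$end)
  }
  cfg <- list(
    schema = system$schema,
    chains = as.list(system$chain_map),
    domains = doms,
    glycans = lapply(system$glycans, function(g) {
      out <- list(chain = g$chain)
      if (!is.null(g$resid)) out$resid <- g$resid
      out
    }),
    residue_sets = lapply(system$residue_sets, function(df) {
      lapply(split(df, df$label), function(s)
        list(chain = s$label[1], resid = s$resid))
    }),
    anchors = lapply(system$anchors, function(a)
      list(chain = a$label, resid = a$resid, atom = a$atom))
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Resolve an annotation anchor to one atom index
#'
#' @param system an `fd_system`.
#' @param atoms topology table.
#' @param name anchor name (e.g., `"cys228_sg"`).
#' @return single integer atom index; error if the anchor resolves to zero or
#'   several atoms (the offending residue identity is reported).
#' @export
resolve_anchor <- function(system, atoms, name) {
  a <- system$anchors[[name]]
  if (is.null(a)) stop_fd("unknown anchor '%s'", name)
  ch <- system$chain_map[[a$label]] %||% a$label
  idx <- select_atoms(atoms, chain = ch, resid = a$resid, name = a$atom)
  if (length(idx) != 1)
    stop_fd("anchor '%s' (chain %s resid %d atom %s) resolves to %d atoms",
            name, ch, a$resid, a$atom, length(idx))
  idx
}

# Integer indices of the atoms of one annotated domain (optionally Ca only).
domain_atoms <- function(system, atoms, label, domain, ca_only = TRUE) {
  dr <- system$domain_ranges
  r <- dr[dr$label == label & dr$domain == domain, ]
  if (nrow(r) == 0) stop_fd("domain %s/%s not annotated", label, domain)
  ch <- system$chain_map[[label]]
  idx <- integer(0)
  for (i in seq_len(nrow(r)))
    idx <- c(idx, select_atoms(atoms, chain = ch, resid = r$start[i]:r$end[i],
                               name = if (ca_only) "CA"))
  idx
}

# Atom indices for a named residue set.
residue_set_atoms <- function(system, atoms, set_name, ca_only = FALSE,
                              heavy = TRUE) {
  df <- system$residue_sets[[set_name]]
  if (is.null(df)) stop_fd("unknown residue set '%s'", set_name)
  idx <- integer(0)
  for (lab in unique(df$label)) {
    ch <- system$chain_map[[lab]] %||% lab
    idx <- c(idx, select_atoms(atoms, chain = ch,
                               resid = df$resid[df$label == lab],
                               name = if (ca_only) "CA", heavy = heavy))
  }
  idx
}

# Atom indices for a named glycan selection (heavy atoms).
glycan_atoms <- function(system, atoms, glycan_name) {
  g <- system$glycans[[glycan_name]]
  if (is.null(g)) stop_fd("unknown glycan selection '%s'", glycan_name)
  select_atoms(atoms, chain = g$chain, resid = g$resid, heavy = TRUE)
}

# ---------------------------------------------------------------- boost log

#' Construct a BoostSeries
#'
#' @param delta_v per-frame total boost energy, kcal/mol (>= 0).
#' @param frame_index aligned 0-based frame numbers.
#' @return object of class `fd_boost`.
#' @export
boost_series <- function(delta_v, frame_index = NULL) {
  delta_v <- as.numeric(delta_v)
  if (any(is.na(delta_v))) stop_fd("boost series contains non-numeric values")
  if (any(delta_v < -1e-9)) stop_fd("boost energies must be >= 0")
  if (is.null(frame_index)) frame_index <- seq_along(delta_v) - 1L
  if (length(frame_index) != length(delta_v))
    stop_fd("frame_index length mismatch")
  structure(list(delta_v = pmax(delta_v, 0), frame_index = as.integer(frame_index)),
            class = "fd_boost")
}

#' Load an aMD boost-energy log
#'
#' Two dialects: `"plain-table"` is whitespace-separated `frame deltaV`
#' (kcal/mol); `"amber-amd-log"` follows the AMBER amd.log layout where
#' comment lines start with `#` and columns 7 and 8 hold the potential and
#' dihedral boost energies. For the AMBER dialect the per-frame boost is the
#' sum of the two components (dual-boost protocol).
#'
#' @param path log file.
#' @param dialect `"plain-table"` (default) or `"amber-amd-log"`.
#' @param traj optional `fd_traj`; when given, a length mismatch is an error.
#' @return an `fd_boost`.
#' @export
load_boost_log <- function(path, dialect = c("plain-table", "amber-amd-log"),
                           traj = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_fd("boost log not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(trimws(lines), "\\s+")
  if (dialect == "plain-table") {
    vals <- vapply(fields, function(f) {
      if (length(f) < 2) stop_fd("malformed boost-log row: need 'frame deltaV'")
      suppressWarnings(as.numeric(f[1:2]))
    }, numeric(2))
    if (any(is.na(vals))) stop_fd("non-numeric row in boost log %s", path)
    bs <- boost_series(vals[2, ], frame_index = as.integer(vals[1, ]))
  } else {
    vals <- vapply(fields, function(f) {
      if (length(f) < 8) stop_fd("amber amd.log row with < 8 columns")
      suppressWarnings(as.numeric(f[7:8]))
    }, numeric(2))
    if (any(is.na(vals))) stop_fd("non-numeric row in boost log %s", path)
    bs <- boost_series(colSums(vals))
  }
  if (!is.null(traj)) check_alignment(bs, traj)
  bs
}

#' Write a BoostSeries as a plain two-column table
#' @param boost an `fd_boost`.
#' @param path output path.
#' @export
write_boost_table <- function(boost, path) {
  writeLines(sprintf("%d %.10g", boost$frame_index, boost$delta_v), path)
  invisible(path)
}

#' Assert that a boost series and a trajectory are frame-aligned
#'
#' Zipping mismatched series is always an error, never silent truncation.
#' @param boost an `fd_boost`.
#' @param traj an `fd_traj`.
#' @export
check_alignment <- function(boost, traj) {
  if (length(boost$delta_v) != n_frames(traj))
    stop_fd("boost series has %d frames but trajectory has %d",
            length(boost$delta_v), n_frames(traj))
  invisible(TRUE)
}
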