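# End-to-end two-system comparison pipeline.
#
# Execution order mirrors the analysis protocol the package implements:
# per-frame descriptors -> reweighting -> free-energy surface ->
# minimum-energy frames -> clustering (medoid) -> interaction / correlation /
# secondary-structure / SASA analyses restricted to the minimum-energy
# frames -> cross-system statistics. The pipeline is a pure function of
# (inputs, config, seed); rerunning with the same config produces
# byte-identical tables.

#' Default analysis parameters
#'
#' Thresholds follow the standard antibody-dynamics protocol: PMF cut
#' 0.5 kcal/mol, RMSD cluster cutoff 6.5 A with at most 10 clusters, heavy
#' atom contact cutoff 4 A, hydrogen-bond frequency cutoff 1%, SASA probe
#' 1.4 A, T = 300 K.
#' @return named list of parameters.
#' @export
pipeline_defaults <- function() {
  list(bins = 60L, fes_range = c(0, 180), pmf_threshold = 0.5,
       cluster_cutoff = 6.5, max_clusters = 10L, contact_cutoff = 4.0,
       hbond_freq_cutoff = 0.01, sasa_probe = 1.4, sasa_points = 240L,
       correlation_threshold = 0.5, temperature = 300,
       maclaurin_order = 10L, rmsd_max_frames = 150L, sasa_max_frames = 10L)
}

load_pipeline_system <- function(cfg) {
  system <- if (inherits(cfg$system, "fd_system")) cfg$system
    else load_annotation(cfg$annotation)
  traj <- if (inherits(cfg$traj, "fd_traj")) cfg$traj
    else load_trajectory(cfg$topology, cfg$trajectory)
  boost <- if (inherits(cfg$boost, "fd_boost")) {
    cfg$boost
  } else if (!is.null(cfg$boost)) {
    load_boost_log(cfg$boost, cfg$boost_dialect %||% "plain-table")
  } else {
    boost_series(rep(0, n_frames(traj)))
  }
  check_alignment(boost, traj)
  list(system = system, traj = traj, boost = boost)
}

write_table <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

# evenly spaced subsample of indices, capped at k
subsample_idx <- function(idx, k) {
  if (length(idx) <= k) return(idx)
  idx[unique(round(seq(1, length(idx), length.out = k)))]
}

analyze_system <- function(name, sysdef, params, out_dir, log) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  traj <- sysdef$traj; system <- sysdef$system; boost <- sysdef$boost

  log(sprintf("[%s] %d frames, %d atoms", name, n_frames(traj),
              dim(traj$coords)[2]))
  desc <- fab_descriptors(traj, system)
  write_table(desc, out_dir, "descriptors.csv")

  w <- maclaurin_weights(boost, temperature = params$temperature,
                         order = params$maclaurin_order)
  fes <- reweighted_fes(desc$theta1, desc$theta2, weights = w,
                        bins = params$bins, range = params$fes_range,
                        temperature = params$temperature)
  write_fes_csv(fes, file.path(out_dir, "fes.csv"))

  mef <- minimum_energy_frames(fes, desc$theta1, desc$theta2,
                               pmf_threshold = params$pmf_threshold)
  if (length(mef) == 0) stop_fd("[%s] no frames below the PMF threshold", name)
  log(sprintf("[%s] %d minimum-energy frames (PMF < %.2f kcal/mol)",
              name, length(mef), params$pmf_threshold))
  write_table(data.frame(frame = desc$frame[mef]), out_dir,
              "min_energy_frames.csv")
  mtraj <- subset_frames(traj, mef)
  mdesc <- desc[mef, , drop = FALSE]
  shape <- names(sort(table(mdesc$shape), decreasing = TRUE))[1]

  # clustering on the minimum-energy frames (capped for the RMSD matrix)
  cl_idx <- subsample_idx(seq_len(n_frames(mtraj)), params$rmsd_max_frames)
  if (length(cl_idx) < length(mef))
    log(sprintf("[%s] RMSD matrix on %d of %d frames (cap)", name,
                length(cl_idx), length(mef)))
  ctraj <- subset_frames(mtraj, cl_idx)
  cl <- if (n_frames(ctraj) >= 2) {
    m <- rmsd_matrix(ctraj)
    gromos_cluster(m, cutoff = params$cluster_cutoff,
                   max_clusters = params$max_clusters)
  } else NULL
  if (!is.null(cl)) {
    write_table(cluster_table(cl, ctraj$frame_index), out_dir, "clusters.csv")
    log(sprintf("[%s] %d clusters, medoid frame %d", name, length(cl$sizes),
                ctraj$frame_index[cl$medoids[1]]))
  }

  # light-chain vs hinge heavy-atom contacts
  lc <- select_atoms(mtraj$atoms,
                     chain = unname(system$chain_map[c("LC1", "LC2")]),
                     heavy = TRUE)
  hinge <- residue_set_atoms(system, mtraj$atoms, "hinge", heavy = TRUE)
  contacts <- count_contacts(mtraj, lc, hinge, cutoff = params$contact_cutoff)
  write_table(data.frame(frame = mtraj$frame_index, contacts = contacts),
              out_dir, "contacts.csv")

  # SASA on a capped, evenly spaced subset of minimum-energy frames
  s_idx <- subsample_idx(seq_len(n_frames(mtraj)), params$sasa_max_frames)
  straj <- subset_frames(mtraj, s_idx)
  sa <- sasa(straj, probe_radius = params$sasa_probe,
             n_sphere_points = params$sasa_points)
  regions <- intersect(c("hinge", "fcgr3a_site", "fcrn_site"),
                       names(system$residue_sets))
  reg <- data.frame(frame = straj$frame_index)
  for (rs in regions) reg[[rs]] <- region_sasa(sa, straj, system, rs)
  write_table(reg, out_dir, "region_sasa.csv")
  patches <- surface_patches(straj, sa, frame = 1L)
  write_table(patches$patches, out_dir, "patches.csv")

  # correlation map on minimum-energy frames
  dcres <- blocks <- NULL
  if (n_frames(mtraj) >= 2) {
    dcres <- dccm(mtraj, system = system)
    utils::write.csv(as.data.frame(dcres$map), file.path(out_dir, "dccm.csv"),
                     row.names = FALSE)
    blocks <- domain_block_summary(dcres,
                                   threshold = params$correlation_threshold)
    write_table(blocks, out_dir, "correlation_blocks.csv")
  }

  # all-atom analyses run only when the topology supports them
  ss_status <- tryCatch({
    ss <- secondary_structure(mtraj)
    utils::write.csv(cbind(ss$residues, as.data.frame(ss$categories)),
                     file.path(out_dir, "secondary_structure.csv"),
                     row.names = FALSE)
    "ok"
  }, error = function(e) conditionMessage(e))
  hb_status <- tryCatch({
    hb <- hydrogen_bonds(mtraj, freq_cutoff = params$hbond_freq_cutoff)
    write_table(hb, out_dir, "hbonds.csv")
    "ok"
  }, error = function(e) conditionMessage(e))
  if (ss_status != "ok")
    log(sprintf("[%s] secondary structure skipped: %s", name, ss_status))
  if (hb_status != "ok")
    log(sprintf("[%s] hydrogen bonds skipped: %s", name, hb_status))

  list(name = name, descriptors = desc, min_energy = mef, mdesc = mdesc,
       shape = shape, clusters = cl,
       medoid_frame = if (!is.null(cl)) ctraj$frame_index[cl$medoids[1]] else NA,
       contacts = contacts, region_sasa = reg, blocks = blocks,
       ss_status = ss_status, hb_status = hb_status,
       n_frames = n_frames(traj), n_min = length(mef))
}

#' Run the full two-system comparison pipeline
#'
#' @param config list with `systems` (named list of two system definitions;
#'   each either in-memory objects `traj`/`system`/`boost` or paths
#'   `topology`/`trajectory`/`annotation`/`boost`), optional `params`
#'   overriding [pipeline_defaults()], `out_dir`, and `seed`.
#' @return invisibly, the summary list (also written as `summary.json`
#'   under `out_dir` together with all stage tables and `run_log.txt`).
#' @export
run_pipeline <- function(config) {
  params <- utils::modifyList(pipeline_defaults(), config$params %||% list())
  out_dir <- config$out_dir %||% stop_fd("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed %||% 1L)
  if (length(config$systems) != 2)
    stop_fd("the pipeline compares exactly two systems")

  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)
  log(sprintf("fabdyn %s", as.character(utils::packageVersion("fabdyn"))))
  ph <- params[order(names(params))]
  log(sprintf("params: %s", jsonlite::toJSON(ph, auto_unbox = TRUE)))

  results <- list()
  for (nm in names(config$systems)) {
    sysdef <- tryCatch(load_pipeline_system(config$systems[[nm]]),
                       error = function(e)
                         stop_fd("stage load [%s]: %s", nm, conditionMessage(e)))
    results[[nm]] <- tryCatch(
      analyze_system(nm, sysdef, params, file.path(out_dir, nm), log),
      error = function(e)
        stop_fd("stage analyze [%s]: %s", nm, conditionMessage(e)))
  }

  # cross-system statistics on the minimum-energy frame sets
  a <- results[[1]]; b <- results[[2]]
  comp <- list()
  for (v in c("theta1", "theta2", "inter_fab_angle", "ch2_distance",
              "glycan_distance")) {
    if (all(is.na(a$mdesc[[v]])) || all(is.na(b$mdesc[[v]]))) next
    comp[[length(comp) + 1L]] <-
      compare_descriptor(v, a$mdesc[[v]], b$mdesc[[v]])
  }
  comp[[length(comp) + 1L]] <-
    compare_descriptor("lc_hinge_contacts", a$contacts, b$contacts)
  for (rs in intersect(names(a$region_sasa), names(b$region_sasa))) {
    if (rs == "frame") next
    comp[[length(comp) + 1L]] <-
      compare_descriptor(paste0("sasa_", rs), a$region_sasa[[rs]],
                         b$region_sasa[[rs]])
  }
  comparison <- do.call(rbind, comp)
  write_table(comparison, out_dir, "comparison.csv")

  flagged <- function(r) {
    if (is.null(r$blocks)) return(character(0))
    bl <- r$blocks[r$blocks$strong & r$blocks$class %in%
                     c("inter-chain", "inter-halves"), ]
    sprintf("%s|%s|%s", bl$block_a, bl$block_b, bl$class)
  }
  summary <- list(
    systems = lapply(results, function(r) list(
      n_frames = r$n_frames, n_min_energy = r$n_min, shape = r$shape,
      medoid_frame = r$medoid_frame,
      secondary_structure = r$ss_status, hydrogen_bonds = r$hb_status,
      flagged_blocks = flagged(r))),
    comparisons = comparison,
    params = ph)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(summary)
}
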