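#' Aggregate a per-residue track by protomer and domain
#'
#' Means, sums and counts of the track per (protomer, domain) cell;
#' masked (NA) values are excluded from mean and sum but counted in
#' `n_masked`.
#'
#' @param track a `PerResidueScalar` or `ConnectivityProfile`
#' @param topology a `TopologySpec`
#' @return data.frame: protomer, domain, mean, sum, count, n_masked
#' @export
aggregate_by_domain <- function(track, topology) {
  value <- if ("value" %in% names(track)) track$value else track$eta
  domain <- assign_domain(track$resid, topology)  # errors outside ranges
  protomer <- unname(topology$chains[track$chain])
  rows <- list()
  for (p in unique(protomer)) {
    for (d in names(topology$domains)) {
      sel <- protomer == p & domain == d
      v <- value[sel]
      rows[[length(rows) + 1L]] <- data.frame(
        protomer = p, domain = d,
        mean = if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_,
        sum = sum(v, na.rm = TRUE),
        count = sum(sel),
        n_masked = sum(is.na(v)))
    }
  }
  do.call(rbind, rows)
}

#' Write a per-residue track into the B-factor column of a PDB file
#'
#' Every atom of a residue gets the residue's track value in the fixed
#' width `%6.2f` B-factor field; masked (NA) residues get 0.00 and are
#' listed in a `<path>.masked.tsv` sidecar.  Values whose magnitude
#' exceeds 999.99 raise an error suggesting a rescale.
#'
#' @param structure a `StructureModel`
#' @param track a `PerResidueScalar` covering the structure's residues
#' @param path output PDB path
#' @return invisibly, the path written
#' @export
write_bfactor_pdb <- function(structure, track, path) {
  key <- paste(structure$atoms$chain, structure$atoms$resid)
  tkey <- paste(track$chain, track$resid)
  idx <- match(key, tkey)
  if (anyNA(idx))
    stop("track does not cover structure residue(s): ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  value <- if ("value" %in% names(track)) track$value else track$eta
  b <- value[idx]
  if (any(abs(b) > 999.99, na.rm = TRUE))
    stop("track value exceeds the B-factor field width (|value| > 999.99);",
         " rescale before writing")
  masked <- track[is.na(value), c("chain", "resid")]
  b[is.na(b)] <- 0
  write_pdb(structure, path, bfactor = b)
  write.table(masked, paste0(path, ".masked.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Analysis configuration for the end-to-end pipeline
#'
#' @param systems named list of systems; each is a list with `topology_pdb`
#'   (path) and `trajectories` (character vector of DCD or multi-model PDB
#'   paths).  For mutant-vs-WT outputs name them `wt` and `mut`.
#' @param topology_config path to a TopologySpec JSON, or a `TopologySpec`
#' @param out_dir output directory
#' @param discard_ns equilibration time to drop per replica
#' @param stride keep one frame in `stride`
#' @param spacing_ps frame spacing of the input trajectories
#' @param gate connectivity mean-distance gate (A, default 5)
#' @param lf_mode LF neighbour window, `"inclusive"` or `"exact"`
#' @param pct_floor mask floor for the percentage difference matrix (A^2)
#' @param hbond_dist,hbond_angle H-bond cutoffs
#' @param mutated_positions optional data.frame(chain, resid) for column
#'   projections; defaults to the topology's mutation list on both chains
#' @export
analysis_config <- function(systems, topology_config, out_dir,
                            discard_ns = 0, stride = 1L, spacing_ps = 10,
                            gate = 5, lf_mode = "inclusive",
                            pct_floor = 1e-6, hbond_dist = 3.0,
                            hbond_angle = 135, mutated_positions = NULL) {
  topo <- if (inherits(topology_config, "TopologySpec")) topology_config
          else read_topology_spec(topology_config)
  for (sys in systems) {
    paths <- c(sys$topology_pdb, sys$trajectories)
    missing_f <- paths[!file.exists(paths)]
    if (length(missing_f) > 0L)
      stop("missing input file(s): ", paste(missing_f, collapse = ", "))
  }
  structure(list(systems = systems, topology = topo, out_dir = out_dir,
                 discard_ns = discard_ns, stride = as.integer(stride),
                 spacing_ps = spacing_ps, gate = gate, lf_mode = lf_mode,
                 pct_floor = pct_floor, hbond_dist = hbond_dist,
                 hbond_angle = hbond_angle,
                 mutated_positions = mutated_positions),
            class = "AnalysisConfig")
}

log_stage <- function(stage, ...) {
  t0 <- proc.time()[["elapsed"]]
  message(sprintf("[mdfluct] %-24s %s", stage,
                  paste(..., sep = " ", collapse = " ")))
  invisible(t0)
}

load_system <- function(sys, cfg) {
  struct <- load_structure(sys$topology_pdb)
  trajs <- lapply(seq_along(sys$trajectories), function(i) {
    p <- sys$trajectories[[i]]
    tr <- if (grepl("\\.dcd$", p, ignore.case = TRUE))
      read_dcd(p, spacing_ps = cfg$spacing_ps, replica = i)
    else read_pdb_frames(p, spacing_ps = cfg$spacing_ps, replica = i)
    select_equilibrated(tr, discard_ns = cfg$discard_ns,
                        stride = cfg$stride)
  })
  meta <- build_meta_trajectory(trajs, struct)
  list(structure = struct, meta = meta)
}

analyze_system <- function(name, loaded, cfg, out_dir) {
  meta <- loaded$meta
  log_stage("compute_df", name, ":", n_frames(meta), "frames x",
            n_residues(loaded$structure), "residues")
  dfres <- compute_df(meta)
  lf <- local_fluctuation_threshold(dfres$df, mode = cfg$lf_mode)
  eta <- connectivity_profile(dfres$df, dfres$mean_dist, lf$LF,
                              gate = cfg$gate)
  rmsf <- compute_rmsf(meta)
  prefix <- file.path(out_dir, name)
  write_matrix_tsv(dfres$df, paste0(prefix, "_df.tsv"))
  write_matrix_tsv(dfres$mean_dist, paste0(prefix, "_mean_dist.tsv"))
  write_track_tsv(eta, cfg$topology, paste0(prefix, "_eta.tsv"))
  write_track_tsv(rmsf, cfg$topology, paste0(prefix, "_rmsf.tsv"))
  write_provenance(meta, paste0(prefix, "_provenance.tsv"))
  ss <- ss_frequency(meta)
  write.table(ss, paste0(prefix, "_ss.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  hb <- tryCatch(
    hbond_occupancy(meta, dist_cut = cfg$hbond_dist,
                    angle_cut = cfg$hbond_angle),
    error = function(e) {
      message("[mdfluct] hbond_occupancy skipped for ", name, ": ",
              conditionMessage(e))
      NULL
    })
  if (!is.null(hb))
    write.table(hb, paste0(prefix, "_hbonds.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  list(df = dfres$df, mean_dist = dfres$mean_dist, lf = lf, eta = eta,
       rmsf = rmsf, structure = loaded$structure)
}

#' Run the full analysis pipeline
#'
#' Executes load -> equilibration trimming -> meta-trajectory assembly ->
#' DF/LF/eta (and, when both a `wt` and a `mut` system are configured,
#' delta-eta, the percentage difference matrix and its column
#' projections) -> RMSF, secondary-structure frequencies and H-bond
#' occupancy -> domain aggregation -> exports, and writes a manifest with
#' checksums of every emitted file.
#'
#' @param config an `AnalysisConfig`
#' @return invisibly, the manifest as a list
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  for (name in names(config$systems)) {
    log_stage("load_system", name)
    loaded <- load_system(config$systems[[name]], config)
    results[[name]] <- analyze_system(name, loaded, config, out_dir)
  }
  if (all(c("wt", "mut") %in% names(config$systems))) {
    log_stage("compare", "mut vs wt")
    wt <- results$wt; mut <- results$mut
    deta <- delta_connectivity(mut$eta, wt$eta)
    pct <- percent_delta_df(mut$df, wt$df, floor = config$pct_floor)
    write_track_tsv(deta, config$topology,
                    file.path(out_dir, "delta_eta.tsv"))
    write_matrix_tsv(pct, file.path(out_dir, "pct_delta_df.tsv"))
    agg <- aggregate_by_domain(deta, config$topology)
    write.table(agg, file.path(out_dir, "delta_eta_by_domain.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    mpos <- config$mutated_positions
    if (is.null(mpos) && length(config$topology$mutations) > 0L)
      mpos <- expand.grid(chain = names(config$topology$chains),
                          resid = config$topology$mutations,
                          stringsAsFactors = FALSE)
    for (i in seq_len(NROW(mpos))) {
      proj <- project_column(pct, mpos$chain[i], mpos$resid[i])
      base <- sprintf("P_mut%s_%d", mpos$chain[i], mpos$resid[i])
      write_track_tsv(proj, config$topology,
                      file.path(out_dir, paste0(base, ".tsv")))
      scale <- max(1, max(abs(proj$value), na.rm = TRUE) / 999)
      proj$value <- proj$value / scale
      write_bfactor_pdb(wt$structure, proj,
                        file.path(out_dir, paste0(base, ".pdb")))
    }
  }
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest <- list(
    parameters = config[c("discard_ns", "stride", "spacing_ps", "gate",
                          "lf_mode", "pct_floor", "hbond_dist",
                          "hbond_angle")],
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("done", length(files), "files in", out_dir)
  invisible(manifest)
}
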