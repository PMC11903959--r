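#' Trajectory: ordered, time-stamped coordinate frames
#'
#' Coordinates are stored as a numeric array of dimension
#' `c(n_atoms, 3, n_frames)`, congruent with a `StructureModel` atom
#' table.  Frame `i` carries timestamp `time_ps[i]`; on a freshly loaded
#' replica this is `spacing_ps * (1:n_frames)` (the first saved frame sits
#' one save interval after time zero).
#'
#' @param xyz numeric array `c(n_atoms, 3, n_frames)`
#' @param spacing_ps frame spacing in picoseconds (> 0)
#' @param replica replica identifier (integer or character)
#' @param time_ps optional explicit per-frame timestamps
#' @export
trajectory <- function(xyz, spacing_ps, replica = 1L, time_ps = NULL) {
  if (length(dim(xyz)) != 3L || dim(xyz)[2] != 3L)
    stop("xyz must be an n_atoms x 3 x n_frames array")
  if (spacing_ps <= 0) stop("frame spacing must be > 0")
  n <- dim(xyz)[3]
  if (is.null(time_ps)) time_ps <- spacing_ps * seq_len(n)
  if (length(time_ps) != n) stop("time_ps length must equal frame count")
  structure(list(xyz = xyz, spacing_ps = spacing_ps, replica = replica,
                 time_ps = time_ps),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory: replica", x$replica, "-", dim(x$xyz)[3], "frames x",
      dim(x$xyz)[1], "atoms @", x$spacing_ps, "ps (",
      total_time_ns(x), "ns )\n")
  invisible(x)
}

#' Number of frames in a Trajectory or MetaTrajectory
#' @param traj a `Trajectory` or `MetaTrajectory`
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' Covered simulation time in nanoseconds
#' @param traj a `Trajectory`
#' @export
total_time_ns <- function(traj) n_frames(traj) * traj$spacing_ps / 1000

#' Discard equilibration and stride a trajectory
#'
#' Keeps frames with timestamp strictly greater than `discard_ns`, then
#' every `stride`-th frame starting from the first retained one.  The
#' output spacing is the input spacing times the stride.  With a 300 ns
#' replica saved every 10 ps (30000 frames), discarding 100 ns and
#' striding by 5 leaves 4000 frames at 50 ps.
#'
#' @param traj a `Trajectory`
#' @param discard_ns equilibration time to drop, in nanoseconds
#' @param stride keep one frame in `stride` (integer >= 1)
#' @export
select_equilibrated <- function(traj, discard_ns, stride = 1L) {
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) stop("stride must be a positive integer")
  keep <- which(traj$time_ps > discard_ns * 1000)
  if (length(keep) == 0L)
    stop("empty selection: discard time (", discard_ns,
         " ns) covers the whole trajectory")
  keep <- keep[seq(1L, length(keep), by = stride)]
  trajectory(traj$xyz[, , keep, drop = FALSE],
             spacing_ps = traj$spacing_ps * stride,
             replica = traj$replica,
             time_ps = traj$time_ps[keep])
}

# ---------------------------------------------------------------------------
# Rigid-body superposition (Kabsch / SVD least squares)

#' Optimal least-squares superposition of one frame onto a reference
#'
#' Computes the rigid rotation + translation minimizing the RMSD of the
#' selected atoms onto the reference (Kabsch algorithm, with the usual
#' determinant correction to exclude reflections), applies it to *all*
#' atoms of the frame, and reports the RMSD over the selection.
#'
#' @param frame n x 3 coordinate matrix
#' @param reference n x 3 coordinate matrix (same atom order)
#' @param selection integer indices of atoms to fit on (>= 3)
#' @return list with `coords` (transformed n x 3 matrix) and `rmsd`
#'   (Angstrom, over the selection)
#' @export
superpose <- function(frame, reference, selection = seq_len(nrow(frame))) {
  if (length(selection) < 3L)
    stop("superposition underdetermined: selection has fewer than 3 atoms")
  if (nrow(frame) != nrow(reference))
    stop("frame and reference have different atom counts")
  x <- frame[selection, , drop = FALSE]
  y <- reference[selection, , drop = FALSE]
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  moved <- sweep(sweep(frame, 2, cx) %*% rot, 2, cy, "+")
  dev <- moved[selection, , drop = FALSE] - y
  list(coords = moved, rmsd = sqrt(mean(rowSums(dev^2))))
}

#' Assemble a superposed meta-trajectory from replicas
#'
#' Concatenates the frames of the given (already equilibration-trimmed)
#' replicas in input order and superposes every frame onto the first frame
#' of the first replica.  The fit selection defaults to the backbone heavy
#' atoms (N, CA, C, O) of residues assigned helix or strand in that
#' reference frame; it is computed once on the reference and frozen.  When
#' the reference has no helix/strand residues (e.g. coarse synthetic
#' systems), all backbone heavy atoms are used instead.
#'
#' @param trajs list of `Trajectory` objects with identical atom layout
#' @param structure the matching `StructureModel`
#' @param selection optional explicit integer atom selection overriding the
#'   secondary-structure rule
#' @return A `MetaTrajectory`: coordinates, per-frame provenance
#'   (replica, source frame index, timestamp) and the superposition record.
#' @export
build_meta_trajectory <- function(trajs, structure, selection = NULL) {
  if (length(trajs) < 1L) stop("need at least one trajectory")
  n_atoms <- vapply(trajs, function(t) dim(t$xyz)[1], integer(1))
  if (length(unique(n_atoms)) != 1L)
    stop("atom-count mismatch across replicas: ",
         paste(n_atoms, collapse = ", "))
  if (n_atoms[1] != nrow(structure$atoms))
    stop("trajectories not congruent with structure (",
         n_atoms[1], " vs ", nrow(structure$atoms), " atoms)")
  ref <- trajs[[1]]$xyz[, , 1]
  if (is.null(selection)) {
    selection <- ss_backbone_selection(structure, ref)
  }
  total <- sum(vapply(trajs, n_frames, integer(1)))
  xyz <- array(NA_real_, c(n_atoms[1], 3, total))
  prov <- data.frame(meta_index = seq_len(total), replica = NA,
                     source_index = NA_integer_, time_ps = NA_real_)
  k <- 0L
  for (tr in trajs) {
    for (f in seq_len(n_frames(tr))) {
      k <- k + 1L
      xyz[, , k] <- superpose(tr$xyz[, , f], ref, selection)$coords
      prov$replica[k] <- tr$replica
      prov$source_index[k] <- f
      prov$time_ps[k] <- tr$time_ps[f]
    }
  }
  structure(list(xyz = xyz, structure = structure, provenance = prov,
                 superposition = list(reference = "replica1/frame1",
                                      selection = selection)),
            class = "MetaTrajectory")
}

# Backbone heavy atoms of helix/strand residues in a reference frame;
# falls back to the full backbone when no residue is helix or strand.
ss_backbone_selection <- function(structure, ref_coords) {
  ss <- tryCatch(suppressWarnings(assign_ss_frame(structure, ref_coords)),
                 error = function(e) NULL)
  sel <- integer(0)
  if (!is.null(ss)) {
    ss_res <- which(ss %in% c("H", "G", "I", "E", "B"))
    if (length(ss_res) > 0L) sel <- backbone_indices(structure, ss_res)
  }
  if (length(sel) < 3L) sel <- backbone_indices(structure)
  if (length(sel) < 3L) sel <- ca_indices(structure)
  sel
}

#' @export
print.MetaTrajectory <- function(x, ...) {
  cat("MetaTrajectory:", n_frames(x), "frames x", dim(x$xyz)[1],
      "atoms from replica(s)", paste(unique(x$provenance$replica),
                                     collapse = ", "), "\n")
  invisible(x)
}

#' Write the provenance table of a meta-trajectory as TSV
#' @param meta a `MetaTrajectory`
#' @param path output path
#' @export
write_provenance <- function(meta, path) {
  write.table(meta$provenance, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Trajectory file I/O: DCD (CHARMM/NAMD binary) and multi-MODEL PDB.

#' Read a DCD trajectory file
#'
#' Reads CHARMM/NAMD-style DCD files (32-bit Fortran record markers,
#' little or big endian autodetected).  Unit-cell blocks, when present,
#' are skipped; fixed-atom DCDs are not supported.
#'
#' @param path path to DCD file
#' @param spacing_ps frame spacing to stamp on the result (default from
#'   the DCD header timestep when readable, else 1)
#' @param replica replica id for the returned `Trajectory`
#' @export
read_dcd <- function(path, spacing_ps = NULL, replica = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  m <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (m != 84L) { endian <- "big"; seek(con, 0)
    m <- readBin(con, "integer", 1, size = 4, endian = endian) }
  if (m != 84L) stop("not a DCD file (bad header record): ", path)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (magic != "CORD") stop("not a coordinate DCD file: ", path)
  icntrl <- readBin(con, "integer", 20, size = 4, endian = endian)
  readBin(con, "integer", 1, size = 4, endian = endian)  # closing marker
  nframes <- icntrl[1]
  has_cell <- icntrl[11] != 0L
  # title block
  tlen <- readBin(con, "integer", 1, size = 4, endian = endian)
  readBin(con, "raw", tlen)
  readBin(con, "integer", 1, size = 4, endian = endian)
  # natom block
  readBin(con, "integer", 1, size = 4, endian = endian)
  natom <- readBin(con, "integer", 1, size = 4, endian = endian)
  readBin(con, "integer", 1, size = 4, endian = endian)
  xyz <- array(NA_real_, c(natom, 3, nframes))
  for (f in seq_len(nframes)) {
    if (has_cell) {
      readBin(con, "integer", 1, size = 4, endian = endian)
      readBin(con, "double", 6, size = 8, endian = endian)
      readBin(con, "integer", 1, size = 4, endian = endian)
    }
    for (ax in 1:3) {
      nb <- readBin(con, "integer", 1, size = 4, endian = endian)
      if (length(nb) == 0L) stop("truncated DCD file: ", path)
      xyz[, ax, f] <- readBin(con, "double", natom, size = 4,
                              endian = endian)
      readBin(con, "integer", 1, size = 4, endian = endian)
    }
  }
  if (is.null(spacing_ps)) spacing_ps <- 1
  trajectory(xyz, spacing_ps = spacing_ps, replica = replica)
}

#' Write a Trajectory to a DCD file
#' @param traj a `Trajectory`
#' @param path output path
#' @export
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  natom <- dim(traj$xyz)[1]; nframes <- n_frames(traj)
  wint <- function(x) writeBin(as.integer(x), con, size = 4,
                               endian = "little")
  wint(84L); writeChar("CORD", con, 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nframes; icntrl[2] <- 1L; icntrl[3] <- 1L
  icntrl[4] <- nframes; icntrl[20] <- 24L  # CHARMM version stamp
  wint(icntrl); wint(84L)
  title <- sprintf("%-80s", "written by mdfluct")
  wint(4L + 80L); wint(1L); writeChar(title, con, 80, eos = NULL)
  wint(4L + 80L)
  wint(4L); wint(natom); wint(4L)
  for (f in seq_len(nframes)) {
    for (ax in 1:3) {
      wint(4L * natom)
      writeBin(as.numeric(traj$xyz[, ax, f]), con, size = 4,
               endian = "little")
      wint(4L * natom)
    }
  }
  invisible(path)
}

#' Read trajectory frames from a multi-MODEL PDB file
#'
#' Every MODEL block becomes one frame; atom order must be identical
#' across models.
#'
#' @param path path to a multi-model PDB file
#' @param spacing_ps frame spacing in ps
#' @param replica replica id
#' @export
read_pdb_frames <- function(path, spacing_ps = 1, replica = 1L) {
  lines <- readLines(path, warn = FALSE)
  tags <- substr(lines, 1, 6)
  model_starts <- which(tags == "MODEL ")
  if (length(model_starts) == 0L) model_starts <- 1L
  frames <- list()
  bounds <- c(model_starts, length(lines) + 1L)
  for (m in seq_along(model_starts)) {
    idx <- seq(bounds[m], bounds[m + 1L] - 1L)
    atom_lines <- idx[tags[idx] == "ATOM  "]
    if (length(atom_lines) == 0L) next
    co <- t(vapply(lines[atom_lines], function(l)
      as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                   substr(l, 47, 54))), numeric(3), USE.NAMES = FALSE))
    frames[[length(frames) + 1L]] <- co
  }
  if (length(frames) == 0L) stop("no coordinate frames in ", path)
  natom <- nrow(frames[[1]])
  if (any(vapply(frames, nrow, integer(1)) != natom))
    stop("atom count varies across MODEL blocks in ", path)
  xyz <- array(unlist(frames), c(natom, 3, length(frames)))
  trajectory(xyz, spacing_ps = spacing_ps, replica = replica)
}
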