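#' Per-residue root mean square fluctuation
#'
#' RMSF about the arithmetic mean structure of the (already superposed)
#' meta-trajectory: for each residue,
#' `RMSF_i = sqrt( mean over frames and selected atoms of |x - <x>|^2 )`.
#' By default only backbone heavy atoms (N, CA, C, O) enter the average,
#' matching the usual reporting convention.
#'
#' @param meta a `MetaTrajectory`
#' @param atoms `"backbone"` (default), `"ca"`, or `"all"`
#' @return A `PerResidueScalar` track labelled `RMSF` (Angstrom).
#' @export
compute_rmsf <- function(meta, atoms = c("backbone", "ca", "all")) {
  atoms <- match.arg(atoms)
  structure_ <- meta$structure
  m <- n_frames(meta)
  if (m < 2L) stop("insufficient data: need at least 2 frames for RMSF")
  sel <- switch(atoms,
                backbone = backbone_indices(structure_),
                ca = ca_indices(structure_),
                all = seq_len(nrow(structure_$atoms)))
  mean_xyz <- apply(meta$xyz[sel, , , drop = FALSE], c(1, 2), mean)
  msd <- numeric(length(sel))
  for (f in seq_len(m)) {
    dev <- meta$xyz[sel, , f] - mean_xyz
    msd <- msd + rowSums(dev^2)
  }
  msd <- msd / m
  res_of <- match(paste(structure_$atoms$chain[sel],
                        structure_$atoms$resid[sel]),
                  paste(structure_$axis$chain, structure_$axis$resid))
  per_res <- vapply(seq_len(nrow(structure_$axis)),
                    function(i) sqrt(mean(msd[res_of == i])), numeric(1))
  track <- data.frame(chain = structure_$axis$chain,
                      resid = structure_$axis$resid,
                      value = per_res)
  attr(track, "label") <- "RMSF"
  class(track) <- c("PerResidueScalar", class(track))
  track
}

# ---------------------------------------------------------------------------
# Hydrogen-bond occupancy

hb_candidates <- function(structure) {
  at <- structure$atoms
  heavy <- which(at$element %in% c("N", "O"))
  hydrogens <- which(at$element == "H")
  if (length(hydrogens) == 0L)
    stop("no hydrogens in topology; H-bond occupancy needs explicit ",
         "hydrogens on donor atoms (add them upstream)")
  xyz <- coords(structure)
  donors <- list()
  for (h in hydrogens) {
    d2 <- rowSums(sweep(xyz[heavy, , drop = FALSE], 2, xyz[h, ])^2)
    near <- heavy[d2 < 1.25^2]
    if (length(near) >= 1L) {
      dn <- near[which.min(d2[match(near, heavy)])]
      donors[[length(donors) + 1L]] <- c(donor = dn, hydrogen = h)
    }
  }
  list(donors = do.call(rbind, donors), acceptors = heavy)
}

#' Hydrogen-bond occupancy over a meta-trajectory
#'
#' A donor--hydrogen...acceptor triple counts as bonded in a frame when
#' the donor-heavy-atom to acceptor distance is at most `dist_cut` and
#' the donor-H-acceptor angle is at least `angle_cut` (the conventional
#' defaults: 3.0 A, 135 degrees).  Donors are N/O atoms with a covalently
#' attached hydrogen (within 1.25 A in the reference geometry); acceptors
#' are all other N/O atoms.  Occupancy is the fraction of frames bonded;
#' only pairs with occupancy > 0 are reported.
#'
#' @param meta a `MetaTrajectory`
#' @param selection optional residue serials; only bonds with donor or
#'   acceptor in these residues are evaluated
#' @param dist_cut heavy-atom distance cutoff in Angstrom (default 3.0)
#' @param angle_cut donor-H-acceptor angle cutoff in degrees (default 135)
#' @param criterion `"heavy"` (default; donor-heavy-atom to acceptor
#'   distance) or `"hydrogen"` (H to acceptor distance)
#' @return data.frame: donor, hydrogen, acceptor labels, occupancy,
#'   mean_dist (A) and mean_angle (deg) over bonded frames, sorted by
#'   occupancy descending.
#' @export
hbond_occupancy <- function(meta, selection = NULL, dist_cut = 3.0,
                            angle_cut = 135, criterion = c("heavy",
                                                           "hydrogen")) {
  criterion <- match.arg(criterion)
  structure_ <- meta$structure
  cand <- hb_candidates(structure_)
  at <- structure_$atoms
  atom_label <- function(i) paste0(at$chain[i], ":", at$resid[i], "@",
                                   at$name[i])
  res_serial <- match(paste(at$chain, at$resid),
                      paste(structure_$axis$chain, structure_$axis$resid))
  m <- n_frames(meta)
  rows <- list()
  for (d in seq_len(nrow(cand$donors))) {
    don <- cand$donors[d, "donor"]; hyd <- cand$donors[d, "hydrogen"]
    for (acc in cand$acceptors) {
      if (acc == don) next
      if (res_serial[acc] == res_serial[don]) next   # intra-residue
      if (!is.null(selection) &&
          !(res_serial[don] %in% selection ||
            res_serial[acc] %in% selection)) next
      slice <- function(i) matrix(meta$xyz[i, , ], nrow = 3)  # 3 x m
      dpos <- slice(don); hp <- slice(hyd); ap <- slice(acc)
      r <- if (criterion == "heavy") sqrt(colSums((dpos - ap)^2))
           else sqrt(colSums((hp - ap)^2))
      u <- dpos - hp; w <- ap - hp
      cosang <- colSums(u * w) / (sqrt(colSums(u^2)) * sqrt(colSums(w^2)))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      bonded <- r <= dist_cut & ang >= angle_cut
      nbond <- sum(bonded)
      dsum <- sum(r[bonded]); asum <- sum(ang[bonded])
      if (nbond > 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          donor = atom_label(don), hydrogen = atom_label(hyd),
          acceptor = atom_label(acc), occupancy = nbond / m,
          mean_dist = dsum / nbond, mean_angle = asum / nbond,
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(donor = character(), hydrogen = character(),
                      acceptor = character(), occupancy = numeric(),
                      mean_dist = numeric(), mean_angle = numeric()))
  out <- do.call(rbind, rows)
  out[order(-out$occupancy), , drop = FALSE]
}
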