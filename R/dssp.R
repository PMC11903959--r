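#' @name secondary_structure
#' @title Eight-class secondary-structure assignment
#'
#' @description
#' Per-frame backbone secondary structure following the Kabsch-Sander
#' scheme.  A backbone hydrogen bond between the C=O of residue i and the
#' N-H of residue j is accepted when the electrostatic proxy energy
#'
#'   E = 27.888 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)   (kcal/mol)
#'
#' is below -0.5 kcal/mol.  The amide hydrogen, when not present in the
#' topology, is reconstructed 1 Angstrom from N along the C=O direction of
#' the preceding residue.  Patterns: an n-turn at i means the C=O of i
#' bonds the N-H of i+n; two consecutive n-turns make a helix (4 -> H,
#' 3 -> G, 5 -> I); bridges between strands give E (ladder) or B
#' (isolated); a lone turn gives T and a Calpha bend above 70 degrees
#' gives S; everything else is '-'.  When several patterns apply the
#' priority is H > E/B > G > I > T > S.
NULL

# Per-residue backbone atom rows: matrix serials x (N, CA, C, O), NA when
# missing.
backbone_table <- function(structure) {
  at <- structure$atoms
  key <- paste(at$chain, at$resid)
  ukey <- paste(structure$axis$chain, structure$axis$resid)
  tab <- matrix(NA_integer_, nrow(structure$axis), 4,
                dimnames = list(NULL, c("N", "CA", "C", "O")))
  for (nm in colnames(tab)) {
    rows <- which(at$name == nm)
    tab[match(key[rows], ukey), nm] <- rows
  }
  tab
}

vnorm <- function(v) sqrt(sum(v^2))

# Cross-distance matrix between two point sets (rows), NA rows propagate.
cross_dist <- function(a, b) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

# Hydrogen-bond matrix HB[i, j]: C=O of residue i accepts the N-H of
# residue j.  xyz: all-atom coordinate matrix for one frame.
hbond_matrix_ks <- function(structure, xyz, bb = backbone_table(structure),
                            energy_cut = -0.5) {
  n <- nrow(bb)
  chain <- structure$axis$chain
  resname <- structure$axis$resname
  # reconstructed amide H for every residue with a preceding C=O
  hpos <- matrix(NA_real_, n, 3)
  at <- structure$atoms
  for (j in seq_len(n)) {
    if (resname[j] == "PRO") next            # no amide hydrogen
    if (is.na(bb[j, "N"])) next
    npos <- xyz[bb[j, "N"], ]
    # explicit H bonded to N takes precedence
    cand <- which(at$element == "H" & at$chain == chain[j] &
                  at$resid == structure$axis$resid[j] &
                  at$name %in% c("H", "HN"))
    if (length(cand) >= 1L) { hpos[j, ] <- xyz[cand[1L], ]; next }
    if (j == 1L || chain[j - 1L] != chain[j]) next
    if (is.na(bb[j - 1L, "C"]) || is.na(bb[j - 1L, "O"])) next
    d <- xyz[bb[j - 1L, "C"], ] - xyz[bb[j - 1L, "O"], ]
    hpos[j, ] <- npos + d / vnorm(d)
  }
  pick <- function(col) {
    out <- matrix(NA_real_, n, 3)
    ok <- !is.na(bb[, col])
    out[ok, ] <- xyz[bb[ok, col], , drop = FALSE]
    out
  }
  cpos <- pick("C"); opos <- pick("O"); npos <- pick("N")
  e <- 27.888 * (1 / cross_dist(opos, npos) + 1 / cross_dist(cpos, hpos) -
                 1 / cross_dist(opos, hpos) - 1 / cross_dist(cpos, npos))
  hb <- !is.na(e) & e < energy_cut
  ca <- ca_indices(structure)
  hb[cross_dist(xyz[ca, , drop = FALSE], xyz[ca, , drop = FALSE]) > 9] <- FALSE
  diag(hb) <- FALSE
  # exclude peptide neighbours within a chain
  idx <- seq_len(n)
  near <- abs(outer(idx, idx, "-")) == 1L &
    outer(chain, chain, "==")
  hb[near] <- FALSE
  hb
}

# Single-frame 8-class assignment; returns character vector over residue
# serials with classes H G I E B T S -
assign_ss_frame <- function(structure, xyz, bb = backbone_table(structure)) {
  n <- nrow(bb)
  chain <- structure$axis$chain
  incomplete <- apply(bb, 1, anyNA)
  if (any(incomplete))
    warning("residues with incomplete backbone assigned '-': ",
            paste(which(incomplete), collapse = ", "))
  if (n < 5L) return(rep("-", n))
  hb <- hbond_matrix_ks(structure, xyz, bb)
  same_chain <- function(i, j) all(chain[i:j] == chain[i])
  turn <- list()                     # turn[[as.character(k)]][i]
  for (k in c(3L, 4L, 5L)) {
    tk <- rep(FALSE, n)
    for (i in seq_len(n - k)) {
      if (same_chain(i, i + k) && hb[i, i + k]) tk[i] <- TRUE
    }
    turn[[as.character(k)]] <- tk
  }
  cls <- rep("-", n)
  mark <- function(idx, code) {
    for (i in idx) if (cls[i] == "-") cls[i] <<- code
    cls
  }
  # helices: two consecutive n-turns, in priority order H, then bridges,
  # then G, I (priority realized by the first-wins mark())
  helix_residues <- function(k) {
    tk <- turn[[as.character(k)]]
    idx <- integer(0)
    for (i in which(tk)) {
      if (i > 1L && tk[i - 1L]) idx <- c(idx, i:(i + k - 1L))
    }
    unique(idx[idx >= 1L & idx <= n])
  }
  cls <- mark(helix_residues(4L), "H")
  # bridges
  hbnd <- function(i, j) i >= 1 && j >= 1 && i <= n && j <= n && hb[i, j]
  bridge <- matrix(FALSE, n, n)
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      if (abs(i - j) <= 2L) next
      par <- (hbnd(i - 1L, j) && hbnd(j, i + 1L)) ||
             (hbnd(j - 1L, i) && hbnd(i, j + 1L))
      anti <- (hbnd(i, j) && hbnd(j, i)) ||
              (hbnd(i - 1L, j + 1L) && hbnd(j - 1L, i + 1L))
      if (par || anti) bridge[i, j] <- TRUE
    }
  }
  has_bridge <- apply(bridge, 1, any)
  extended <- rep(FALSE, n)
  for (i in which(has_bridge)) {
    neighbours <- c(i - 1L, i + 1L)
    neighbours <- neighbours[neighbours >= 1L & neighbours <= n]
    if (any(has_bridge[neighbours])) extended[i] <- TRUE
  }
  cls <- mark(which(extended), "E")
  cls <- mark(which(has_bridge & !extended), "B")
  cls <- mark(helix_residues(3L), "G")
  cls <- mark(helix_residues(5L), "I")
  # turns: residues strictly inside any n-turn
  turn_res <- integer(0)
  for (k in c(3L, 4L, 5L)) {
    for (i in which(turn[[as.character(k)]]))
      turn_res <- c(turn_res, (i + 1L):(i + k - 1L))
  }
  turn_res <- unique(turn_res[turn_res >= 1L & turn_res <= n])
  cls <- mark(turn_res, "T")
  # bends: Calpha direction change above 70 degrees
  ca <- ca_indices(structure)
  for (i in 3:(n - 2)) {
    if (!same_chain(i - 2L, i + 2L)) next
    u <- xyz[ca[i], ] - xyz[ca[i - 2L], ]
    v <- xyz[ca[i + 2L], ] - xyz[ca[i], ]
    cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    if (ang > 70) cls <- mark(i, "S")
  }
  cls[incomplete] <- "-"
  cls
}

SS_CLASSES <- c("H", "G", "I", "E", "B", "T", "S", "-")

#' Secondary-structure class frequencies over a meta-trajectory
#'
#' Assigns the eight Kabsch-Sander classes per frame and aggregates the
#' per-residue class frequencies (each row sums to 1).
#'
#' @param meta a `MetaTrajectory`
#' @return An `SSFrequency`: data.frame with chain, resid and one column
#'   per class (`coil` for '-').
#' @export
ss_frequency <- function(meta) {
  structure_ <- meta$structure
  bb <- backbone_table(structure_)
  n <- nrow(structure_$axis)
  counts <- matrix(0, n, length(SS_CLASSES),
                   dimnames = list(NULL, SS_CLASSES))
  nf <- n_frames(meta)
  for (f in seq_len(nf)) {
    cls <- suppressWarnings(assign_ss_frame(structure_, meta$xyz[, , f], bb))
    for (k in SS_CLASSES) counts[, k] <- counts[, k] + (cls == k)
  }
  freq <- counts / nf
  out <- data.frame(chain = structure_$axis$chain,
                    resid = structure_$axis$resid,
                    freq, check.names = FALSE)
  names(out)[names(out) == "-"] <- "coil"
  class(out) <- c("SSFrequency", class(out))
  out
}
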