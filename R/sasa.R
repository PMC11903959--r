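#' @name sasa
#' @title Solvent accessible surface area (Shrake-Rupley)
#'
#' @description
#' Numerical SASA by sphere sampling: each atom is inflated by the probe
#' radius (water, 1.4 A) and covered with quasi-uniform test points (a
#' golden-section spiral); a point is accessible when it lies outside
#' every neighbouring inflated sphere.  The accessible fraction times the
#' inflated sphere area gives the atom's SASA.  Relative (per-residue)
#' SASA divides the residue's summed atom SASA in context by the
#' residue-type theoretical maximum from a Gly-X-Gly reference table
#' (Tien et al. 2013), clamped to [0, 1].
NULL

VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80)

# Theoretical Gly-X-Gly maximum accessibilities, A^2 (Tien et al. 2013)
MAX_ACC <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
             GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
             LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
             SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Per-atom solvent accessible surface area
#'
#' @param structure a `StructureModel`
#' @param probe probe radius in Angstrom (default 1.4)
#' @param n_points sphere sampling points per atom (default 960)
#' @return numeric vector of atom SASA values (A^2)
#' @export
sasa_atoms <- function(structure, probe = 1.4, n_points = 960L) {
  xyz <- coords(structure)
  rad <- atom_radius(structure$atoms$element) + probe
  n <- nrow(xyz)
  pts <- golden_spiral(n_points)
  out <- numeric(n)
  max_r <- max(rad)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rad + rad[i])^2 & seq_len(n) != i)
    sphere <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      hit <- rowSums(sweep(sphere, 2, xyz[j, ])^2) < rad[j]^2
      acc <- acc & !hit
      if (!any(acc)) break
    }
    out[i] <- mean(acc) * 4 * pi * rad[i]^2
  }
  out
}

#' Relative solvent accessibility of one residue in context
#'
#' @param structure a `StructureModel` (full context: all chains)
#' @param chain chain id of the residue
#' @param resid residue number
#' @param probe probe radius in Angstrom (default 1.4)
#' @param n_points sphere sampling points per atom (default 960)
#' @return fraction in [0, 1]: residue SASA over its type maximum
#' @export
relative_sasa <- function(structure, chain, resid, probe = 1.4,
                          n_points = 960L) {
  serial <- residue_serial(structure, chain, resid)
  resname <- structure$axis$resname[serial]
  if (!resname %in% names(MAX_ACC))
    stop("no maximum-accessibility reference for residue type ", resname)
  per_atom <- sasa_atoms(structure, probe = probe, n_points = n_points)
  at <- structure$atoms
  rows <- which(at$chain == chain & at$resid == resid & at$element != "H")
  total <- sum(per_atom[rows])
  min(1, max(0, total / MAX_ACC[[resname]]))
}
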