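# Ideal-geometry backbone builder (NeRF internal-coordinate chain
# extension) used for secondary-structure and H-bond geometry tests.

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# Place atom D given A-B-C, |CD| = r, angle(BCD) = theta (deg),
# torsion(ABCD) = chi (deg).
place_atom <- function(a, b, c, r, theta, chi) {
  theta <- theta * pi / 180; chi <- chi * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  nv <- cross3(b - a, bc); nv <- nv / sqrt(sum(nv^2))
  mv <- cross3(nv, bc)
  d <- c(-r * cos(theta), r * sin(theta) * cos(chi),
         r * sin(theta) * sin(chi))
  c + d[1] * bc + d[2] * mv + d[3] * nv
}

# Poly-alanine backbone (N, CA, C, O per residue) with uniform phi/psi.
# Ideal alpha helix: phi = -57, psi = -47; extended strand: -135 / 135.
build_peptide <- function(n, phi, psi, chain = "A") {
  stopifnot(n >= 2)
  atoms <- list()
  npos <- c(0, 0, 0)
  capos <- c(1.458, 0, 0)
  theta <- 111.2 * pi / 180
  cpos <- capos + 1.525 * c(-cos(theta), sin(theta), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      npos <- place_atom(prev$n, prev$ca, prev$c, 1.329, 116.2, psi)
      capos <- place_atom(prev$ca, prev$c, npos, 1.458, 121.7, 180)
      cpos <- place_atom(prev$c, npos, capos, 1.525, 111.2, phi)
    }
    opos_next_n <- place_atom(npos, capos, cpos, 1.329, 116.2, psi)
    # carbonyl O opposite the next N in the peptide plane
    opos <- place_atom(npos, capos, cpos, 1.231, 120.8, psi + 180)
    atoms[[i]] <- data.frame(
      name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
      resid = i, resname = "ALA", chain = chain,
      x = c(npos[1], capos[1], cpos[1], opos[1]),
      y = c(npos[2], capos[2], cpos[2], opos[2]),
      z = c(npos[3], capos[3], cpos[3], opos[3]),
      stringsAsFactors = FALSE)
    prev <- list(n = npos, ca = capos, c = cpos)
  }
  structure_model(do.call(rbind, atoms))
}
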