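#' Elastic spring graph over Calpha sites
#'
#' Stand-in for the physical coupling an MD force field provides: nodes
#' are the Calpha sites of a `StructureModel`, edges carry force constants
#' (kcal/mol/A^2) between sites within a distance cutoff, plus any
#' user-added long-range couplings.  The graph must be connected within
#' each protomer.
#'
#' @param structure a `StructureModel`
#' @param cutoff distance cutoff in Angstrom for automatic contacts
#'   (default 10)
#' @param k force constant assigned to contacts (default 1)
#' @return A `SpringGraph` with the symmetric weight matrix `kmat` over
#'   residue serials.
#' @export
build_spring_graph <- function(structure, cutoff = 10, k = 1) {
  ca <- coords(structure)[ca_indices(structure), , drop = FALSE]
  d <- as.matrix(dist(ca))
  kmat <- (d <= cutoff) * k
  diag(kmat) <- 0
  spring_graph(kmat, structure)
}

#' Construct a SpringGraph from an explicit weight matrix
#' @param kmat symmetric non-negative N x N force-constant matrix
#' @param structure the matching `StructureModel`
#' @export
spring_graph <- function(kmat, structure) {
  n <- n_residues(structure)
  if (!isTRUE(all.equal(kmat, t(kmat)))) stop("spring matrix must be symmetric")
  if (any(kmat < 0)) stop("spring constants must be non-negative")
  if (nrow(kmat) != n) stop("spring matrix size does not match residue count")
  g <- structure(list(kmat = kmat, axis = structure$axis),
                 class = "SpringGraph")
  check_protomer_connectivity(g)
  g
}

graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] > 0 & comp == 0L))
    }
  }
  comp
}

check_protomer_connectivity <- function(springs) {
  for (ch in unique(springs$axis$chain)) {
    idx <- which(springs$axis$chain == ch)
    sub <- springs$kmat[idx, idx, drop = FALSE]
    if (max(graph_components(sub)) > 1L)
      stop("spring graph disconnected within protomer ", ch)
  }
  invisible(springs)
}

#' Scale the couplings around one site (synthetic point mutation)
#'
#' Scales all spring constants incident to the given residue by `factor`,
#' leaving every other edge untouched.  Factors below 1 emulate the local
#' destabilization a damaging substitution causes; factor 0 isolates the
#' site (which downstream sampling rejects as disconnected).
#'
#' @param springs a `SpringGraph`
#' @param position residue serial, or `c(chain, resid)` character pair
#' @param factor non-negative scale factor
#' @export
perturb_springs <- function(springs, position, factor) {
  if (factor < 0) stop("factor must be >= 0")
  i <- resolve_position(springs$axis, position)
  kmat <- springs$kmat
  kmat[i, ] <- kmat[i, ] * factor
  kmat[, i] <- kmat[, i] * factor
  out <- structure(list(kmat = kmat, axis = springs$axis),
                   class = "SpringGraph")
  out
}

resolve_position <- function(axis, position) {
  if (length(position) == 2L) {
    i <- which(axis$chain == position[[1L]] &
               axis$resid == as.integer(position[[2L]]))
  } else {
    i <- as.integer(position)
    if (is.na(i) || i < 1L || i > nrow(axis)) i <- integer(0)
  }
  if (length(i) != 1L)
    stop("unknown position: ", paste(position, collapse = ":"))
  i
}

#' Ensemble sampling specification
#'
#' Describes the stochastic ensemble to draw: number of independent
#' replicas, frames per replica, frame spacing, a temperature factor
#' setting the displacement scale (A^2 per unit inverse force constant),
#' and a mandatory seed.  The defaults mirror the production protocol the
#' analysis expects (three replicas saved every 10 ps); frame counts are
#' chosen per use since frames are independent draws and only set
#' sampling precision.
#'
#' @param n_replicas number of replicas (default 3)
#' @param n_frames frames per replica
#' @param spacing_ps frame spacing in ps (default 10)
#' @param temperature_factor displacement variance scale (default 1)
#' @param seed integer random seed (mandatory)
#' @export
ensemble_spec <- function(n_replicas = 3L, n_frames = 1000L,
                          spacing_ps = 10, temperature_factor = 1,
                          seed) {
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory for reproducible ensembles")
  vals <- c(n_replicas, n_frames, spacing_ps, temperature_factor)
  if (any(vals <= 0)) stop("all EnsembleSpec parameters must be positive")
  structure(list(n_replicas = as.integer(n_replicas),
                 n_frames = as.integer(n_frames),
                 spacing_ps = spacing_ps,
                 temperature_factor = temperature_factor,
                 seed = as.integer(seed)),
            class = "EnsembleSpec")
}

#' Sample a Gaussian-network ensemble of trajectories
#'
#' Frames are the mean structure plus independent Gaussian displacements
#' whose covariance (per Cartesian component, isotropic) is the
#' temperature factor times the Moore-Penrose pseudo-inverse of the
#' weighted Kirchhoff (connectivity) matrix of the spring graph.  Rigid
#' translational zero modes (one per connected component) are excluded;
#' any further singularity means a disconnected protomer and is an error.
#' Each residue's displacement is applied rigidly to all its atoms.
#' Replica seeds are derived deterministically from `spec$seed`.
#'
#' @param structure a `StructureModel` (the mean geometry)
#' @param springs a `SpringGraph` over the same residues
#' @param spec an `EnsembleSpec`
#' @return list of `Trajectory`, one per replica
#' @export
sample_gnm_trajectory <- function(structure, springs, spec) {
  check_protomer_connectivity(springs)
  n <- n_residues(structure)
  kmat <- springs$kmat
  kirch <- diag(rowSums(kmat)) - kmat
  eig <- eigen(kirch, symmetric = TRUE)
  tol <- max(eig$values) * 1e-9
  n_zero <- sum(eig$values < tol)
  n_comp <- max(graph_components(kmat))
  if (n_zero > n_comp)
    stop("Kirchhoff matrix singular beyond rigid zero modes; ",
         "spring graph is effectively disconnected")
  live <- eig$values >= tol
  v <- eig$vectors[, live, drop = FALSE]
  amp <- sqrt(spec$temperature_factor / eig$values[live])
  ref <- coords(structure)
  res_of_atom <- match(paste(structure$atoms$chain, structure$atoms$resid),
                       paste(structure$axis$chain, structure$axis$resid))
  lapply(seq_len(spec$n_replicas), function(r) {
    set.seed((spec$seed + 10007L * r) %% 2147483647L)
    m <- spec$n_frames
    xyz <- array(NA_real_, c(nrow(ref), 3, m))
    for (ax in 1:3) {
      z <- matrix(rnorm(length(amp) * m), length(amp), m)
      disp <- v %*% (amp * z)                    # residues x frames
      xyz[, ax, ] <- ref[, ax] + disp[res_of_atom, , drop = FALSE]
    }
    trajectory(xyz, spacing_ps = spec$spacing_ps, replica = r)
  })
}

#' Build a toy two-protomer structure with domains
#'
#' Generates a compact serpentine fold of Calpha sites (3.8 A between
#' consecutive residues, wider spacing between rows and layers so that
#' non-adjacent residues are typically > 5 A apart), adds minimal
#' backbone N, C, O atoms per residue, and duplicates the fold as a
#' second chain placed close enough for interface contacts within the
#' default 10 A spring cutoff.  Coordinates carry a small seeded jitter
#' so the fold is not degenerate.
#'
#' @param residues_per_protomer number of residues per chain (>= 10)
#' @param domains named list of ranges over 1..residues_per_protomer that
#'   must tile the span; default splits the chain into NTD/LMD/SMD/CTD
#'   quarters in proportions matching the real protein
#' @param seed integer seed for the jitter
#' @param offset numbering offset recorded in the returned TopologySpec
#' @return list with `structure` (a `StructureModel`) and `topology`
#'   (a `TopologySpec`)
#' @export
build_toy_dimer <- function(residues_per_protomer = 50L, domains = NULL,
                            seed = 1L, offset = 0L) {
  n <- as.integer(residues_per_protomer)
  if (n < 10L) stop("residues_per_protomer must be >= 10")
  if (is.null(domains)) {
    cuts <- round(cumsum(c(226, 160, 116, 133) / 635 * n))
    cuts[4] <- n
    domains <- list(NTD = c(1L, cuts[1]),
                    LMD = c(cuts[1] + 1L, cuts[2]),
                    SMD = c(cuts[2] + 1L, cuts[3]),
                    CTD = c(cuts[3] + 1L, cuts[4]))
  }
  topo <- topology_spec(chains = c(A = "A", B = "B"), offset = offset,
                        domains = domains)
  if (topo$span[1] != 1L || topo$span[2] != n)
    stop("domain ranges must cover the full span 1-", n)
  set.seed(seed %% 2147483647L)
  row_len <- max(4L, ceiling(sqrt(n)))
  ca <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    row <- (i - 1L) %/% row_len
    col <- (i - 1L) %% row_len
    if (row %% 2L == 1L) col <- row_len - 1L - col   # serpentine
    layer <- row %/% 4L
    ca[i, ] <- c(col * 3.8, (row %% 4L) * 6.0, layer * 6.0) +
      runif(3, -0.25, 0.25)
  }
  shift <- c(0, 0, max(ca[, 3]) + 8.0)   # interface gap ~8 A < spring cutoff
  build_chain <- function(chain, offset_xyz) {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      p <- ca[i, ] + offset_xyz
      d <- if (i < n) ca[i + 1L, ] - ca[i, ] else ca[i, ] - ca[i - 1L, ]
      d <- d / sqrt(sum(d^2))
      perp <- c(-d[2], d[1], 0)
      if (sum(perp^2) < 1e-8) perp <- c(1, 0, 0)
      perp <- perp / sqrt(sum(perp^2))
      npos <- p - 1.2 * d + 0.7 * perp
      hpos <- npos - 1.0 * perp            # amide hydrogen (H-bond donor)
      cpos <- p + 1.2 * d + 0.7 * perp
      opos <- cpos + 1.23 * perp
      rows[[i]] <- data.frame(
        name = c("N", "H", "CA", "C", "O"),
        element = c("N", "H", "C", "C", "O"),
        resid = i, resname = "ALA", chain = chain,
        x = c(npos[1], hpos[1], p[1], cpos[1], opos[1]),
        y = c(npos[2], hpos[2], p[2], cpos[2], opos[2]),
        z = c(npos[3], hpos[3], p[3], cpos[3], opos[3]),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  atoms <- rbind(build_chain("A", c(0, 0, 0)), build_chain("B", shift))
  list(structure = structure_model(atoms), topology = topo)
}

#' Write a synthetic fixture bundle to disk
#'
#' Layout: `topology.pdb`, `rep<k>.dcd` per replica, `topology.json`, and
#' `manifest.json` recording parameters.  Round-trips through the loaders
#' to coordinate precision of the formats (1e-3 A for PDB, float32 for
#' DCD).
#'
#' @param structure a `StructureModel`
#' @param topology a `TopologySpec`
#' @param trajectories list of `Trajectory`
#' @param out_dir output directory (created if needed)
#' @param params optional list stored in the manifest (e.g. the
#'   `EnsembleSpec` used)
#' @return invisibly, the vector of files written
#' @export
write_fixture <- function(structure, topology, trajectories, out_dir,
                          params = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  files <- character(0)
  p <- file.path(out_dir, "topology.pdb")
  write_pdb(structure, p); files <- c(files, p)
  p <- file.path(out_dir, "topology.json")
  write_topology_spec(topology, p); files <- c(files, p)
  for (i in seq_along(trajectories)) {
    p <- file.path(out_dir, sprintf("rep%d.dcd", i))
    write_dcd(trajectories[[i]], p); files <- c(files, p)
  }
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(files = basename(files),
         n_replicas = length(trajectories),
         spacing_ps = trajectories[[1]]$spacing_ps,
         params = params),
    p, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, p)
  invisible(files)
}
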