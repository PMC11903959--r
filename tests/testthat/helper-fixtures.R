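# Shared builders and independent oracles for the test suite.

# Minimal structure of CA-only residues at given coordinates.
ca_structure <- function(xyz, chain = rep("A", nrow(xyz)),
                         resid = NULL) {
  if (is.null(resid)) {
    resid <- integer(nrow(xyz))
    for (ch in unique(chain)) resid[chain == ch] <- seq_len(sum(chain == ch))
  }
  structure_model(data.frame(
    name = "CA", element = "C", resid = resid, resname = "ALA",
    chain = chain, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE))
}

# Wrap a coordinate array as a MetaTrajectory without superposition
# (for per-frame statistics that do not require alignment).
make_meta <- function(struct, xyz) {
  structure(list(
    xyz = xyz, structure = struct,
    provenance = data.frame(meta_index = seq_len(dim(xyz)[3]),
                            replica = 1L,
                            source_index = seq_len(dim(xyz)[3]),
                            time_ps = seq_len(dim(xyz)[3])),
    superposition = list(reference = "none", selection = integer(0))),
    class = "MetaTrajectory")
}

# Constant-coordinate trajectory from a structure (bookkeeping tests).
constant_trajectory <- function(struct, n_frames, spacing_ps, replica = 1L) {
  ref <- coords(struct)
  xyz <- array(ref, c(nrow(ref), 3, n_frames))
  trajectory(xyz, spacing_ps = spacing_ps, replica = replica)
}

# Random rigid motion (proper rotation + translation).
random_rigid <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rot = q, shift = rnorm(3, sd = 10))
}

apply_rigid <- function(frame, rig) {
  sweep(frame %*% rig$rot, 2, rig$shift, "+")
}

# N-H...O=C probe geometry: donor N at origin, H towards the acceptor.
hb_probe_structure <- function(no_dist) {
  structure_model(data.frame(
    name = c("N", "H", "CA", "O", "C", "CA"),
    element = c("N", "H", "C", "O", "C", "C"),
    resid = c(1L, 1L, 1L, 2L, 2L, 2L),
    resname = "ALA", chain = c("A", "A", "A", "B", "B", "B"),
    x = c(0, 1, -1.5, no_dist, no_dist + 1.23, no_dist + 1.5),
    y = c(0, 0, 0.5, 0, 0, 1.0), z = 0, stringsAsFactors = FALSE))
}

# --- independent oracles -----------------------------------------------

# DF + mean distance by explicit per-pair, per-frame double loop.
oracle_df <- function(struct, xyz) {
  ca <- ca_indices(struct)
  n <- length(ca); m <- dim(xyz)[3]
  dfm <- matrix(0, n, n); md <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(colSums((matrix(xyz[ca[i], , ], 3) -
                         matrix(xyz[ca[j], , ], 3))^2))
      mu <- sum(d) / m
      v <- sum((d - mu)^2) / m        # population variance
      dfm[i, j] <- dfm[j, i] <- v
      md[i, j] <- md[j, i] <- mu
    }
  }
  list(df = dfm, mean_dist = md)
}

# LF with explicit terminus clipping.
oracle_lf <- function(dfm, chain, mode = "inclusive") {
  n <- nrow(dfm)
  offs <- if (mode == "inclusive") c(-2, -1, 1, 2) else c(-2, 2)
  lf_i <- numeric(n)
  for (i in seq_len(n)) {
    pos <- which(chain == chain[i])
    p <- match(i, pos)
    nb <- p + offs
    nb <- nb[nb >= 1 & nb <= length(pos)]
    lf_i[i] <- mean(dfm[i, pos[nb]])
  }
  list(LF = mean(lf_i), LF_i = lf_i)
}

# Connectivity count by explicit pair loop.
oracle_eta <- function(dfm, md, lf, gate = 5) {
  n <- nrow(dfm)
  eta <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i) next
      if (md[i, j] > gate && dfm[i, j] < lf) eta[i] <- eta[i] + 1L
    }
  }
  eta
}

# A GNM test ensemble: toy dimer + springs + one sampled meta-trajectory.
gnm_fixture <- function(n_res = 15, n_frames = 300, seed = 11,
                        factor = NULL, mutated = NULL, tf = 1) {
  toy <- build_toy_dimer(n_res, seed = seed)
  springs <- build_spring_graph(toy$structure)
  if (!is.null(factor))
    springs <- perturb_springs(springs, mutated, factor)
  spec <- ensemble_spec(n_replicas = 1, n_frames = n_frames,
                        temperature_factor = tf, seed = seed + 1)
  tr <- sample_gnm_trajectory(toy$structure, springs, spec)[[1]]
  meta <- make_meta(toy$structure, tr$xyz)
  list(toy = toy, springs = springs, meta = meta)
}
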