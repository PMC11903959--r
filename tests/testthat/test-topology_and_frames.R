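# Structure parsing, numbering/domain semantics, frame selection,
# superposition and meta-trajectory assembly.

test_that("load_structure parses a toy dimer PDB and preserves chains", {
  toy <- build_toy_dimer(50, seed = 4)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(toy$structure, p)
  s <- load_structure(p)
  expect_equal(n_residues(s), 100L)
  expect_length(ca_indices(s), 100L)
  expect_setequal(unique(s$axis$chain), c("A", "B"))
  expect_equal(nrow(s$atoms), nrow(toy$structure$atoms))
})

test_that("malformed and unsupported PDB records are rejected", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1      1.0"), p)  # truncated
  expect_error(load_structure(p), "malformed ATOM record at line 1")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  1.00  0.00           C"
  ), p)
  expect_error(load_structure(p), "alternate location")
  writeLines(c(
    "ATOM      1  CA  ALA A   1A      1.000   0.000   0.000  1.00  0.00           C"
  ), p)
  expect_error(load_structure(p), "insertion code")
})

test_that("structures validate CA uniqueness and coordinate sanity", {
  df <- data.frame(name = c("CA", "CA"), element = "C", resid = 1L,
                   resname = "ALA", chain = "A", x = 0, y = 0, z = 0)
  expect_error(structure_model(df), "2 CA atoms")
  df2 <- data.frame(name = "CA", element = "C", resid = 1L,
                    resname = "ALA", chain = "A", x = NaN, y = 0, z = 0)
  expect_error(structure_model(df2), "non-finite")
  df3 <- data.frame(name = c("N", "CA"), element = c("N", "C"), resid = 1L,
                    resname = "ALA", chain = "A", x = 0:1, y = 0, z = 0)
  s <- structure_model(df3)
  expect_length(ca_indices(s), 1L)
})

test_that("numbering offset maps model<->human for all five mutations", {
  topo <- topology_spec()   # zTrap1-style: offset 15, span 85-719
  model <- c(275L, 396L, 571L, 586L, 615L)
  human <- c(260L, 381L, 556L, 571L, 600L)
  expect_equal(map_numbering(model, "model_to_human", topo), human)
  expect_equal(map_numbering(human, "human_to_model", topo), model)
  # round trip is the identity
  expect_equal(
    map_numbering(map_numbering(260L, "human_to_model", topo),
                  "model_to_human", topo), 260L)
  expect_error(map_numbering(60L, "model_to_human", topo), "outside")
  expect_error(map_numbering(720L, "model_to_human", topo), "outside")
})

test_that("assign_domain follows the declared ranges", {
  topo <- topology_spec()
  expect_equal(assign_domain(300L, topo), "NTD")
  expect_equal(assign_domain(311L, topo), "LMD")
  expect_equal(assign_domain(471L, topo), "SMD")
  expect_equal(assign_domain(719L, topo), "CTD")
  expect_error(assign_domain(84L, topo), "outside all domain ranges")
})

test_that("topology_spec validates domain contiguity and mutations", {
  expect_error(topology_spec(domains = list(A = c(1, 10), B = c(12, 20))),
               "contiguous")
  expect_error(topology_spec(domains = list(A = c(1, 10), B = c(8, 20))),
               "contiguous")
  expect_error(topology_spec(mutations = 50L), "outside declared domain")
  p <- withr::local_tempfile(fileext = ".json")
  topo <- topology_spec(mutations = 615L)
  write_topology_spec(topo, p)
  back <- read_topology_spec(p)
  expect_equal(back$offset, topo$offset)
  expect_equal(back$domains, topo$domains)
  expect_equal(back$mutations, topo$mutations)
})

test_that("select_equilibrated reproduces the production frame counts", {
  s <- ca_structure(matrix(rnorm(9), 3))
  tr <- constant_trajectory(s, 30000L, spacing_ps = 10)   # 300 ns
  expect_equal(total_time_ns(tr), 300)
  eq <- select_equilibrated(tr, discard_ns = 100, stride = 5L)
  expect_equal(n_frames(eq), 4000L)
  expect_equal(eq$spacing_ps, 50)
  # identity selection
  id <- select_equilibrated(tr, 0, 1L)
  expect_equal(n_frames(id), 30000L)
  # degenerate cases
  small <- constant_trajectory(s, 10L, spacing_ps = 10)
  expect_error(select_equilibrated(small, discard_ns = 1), "empty selection")
  expect_error(select_equilibrated(small, 0, stride = 0L), "positive integer")
})

test_that("frame bookkeeping matches a naive filter oracle", {
  s <- ca_structure(matrix(rnorm(9), 3))
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(50:400, 1)
    spacing <- sample(c(1, 2, 5, 10), 1)
    stride <- sample(1:6, 1)
    discard_ns <- runif(1, 0, n * spacing / 1000 * 0.9)
    tr <- constant_trajectory(s, n, spacing_ps = spacing)
    # oracle: frame-by-frame filter
    times <- spacing * seq_len(n)
    kept <- times[times > discard_ns * 1000]
    kept <- kept[seq(1, length(kept), by = stride)]
    eq <- select_equilibrated(tr, discard_ns, stride)
    expect_equal(n_frames(eq), length(kept))
    expect_equal(eq$time_ps, kept)
  }
})

test_that("superpose removes rigid motion and reports RMSD", {
  set.seed(7)
  ref <- matrix(rnorm(30), 10)
  out <- superpose(ref, ref)
  expect_equal(out$rmsd, 0, tolerance = 1e-12)
  rig <- random_rigid()
  moved <- apply_rigid(ref, rig)
  out2 <- superpose(moved, ref)
  expect_lt(out2$rmsd, 1e-8)
  expect_equal(out2$coords, ref, tolerance = 1e-8)
  expect_error(superpose(ref, ref, selection = 1:2), "underdetermined")
  expect_error(superpose(ref, ref[1:5, ]), "different atom counts")
})

test_that("superpose matches a brute-force rotation-grid oracle", {
  # 4-atom pair with internal distortion: optimal RMSD cannot be zero and
  # must be at or below the best rotation found on a coarse grid.
  ref <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  frame <- rbind(c(0, 0, 0), c(2.4, 0, 0), c(0, 1.7, 0.2), c(0.1, 0, 2.1))
  set.seed(1)
  frame <- apply_rigid(frame, random_rigid())
  fit <- superpose(frame, ref, selection = 1:4)
  grid <- seq(0, 2 * pi, length.out = 25)[-25]
  cf <- sweep(frame, 2, colMeans(frame))
  cr <- sweep(ref, 2, colMeans(ref))
  best <- Inf
  for (a in grid) for (b in grid) for (g in grid) {
    rz <- function(t) rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0),
                            c(0, 0, 1))
    ry <- function(t) rbind(c(cos(t), 0, sin(t)), c(0, 1, 0),
                            c(-sin(t), 0, cos(t)))
    rot <- rz(a) %*% ry(b) %*% rz(g)
    r <- sqrt(mean(rowSums((cf %*% rot - cr)^2)))
    if (r < best) best <- r
  }
  expect_gt(fit$rmsd, 0.05)              # genuinely distorted
  expect_lte(fit$rmsd, best + 1e-12)     # optimal beats every grid point
  expect_lt(best - fit$rmsd, 0.05)       # coarse grid comes close
})

test_that("superposition is rigid: inter-atomic distances unchanged", {
  set.seed(13)
  ref <- matrix(rnorm(45), 15)
  for (i in 1:10) {
    frame <- apply_rigid(matrix(rnorm(45), 15), random_rigid())
    out <- superpose(frame, ref)
    expect_equal(as.numeric(dist(out$coords)), as.numeric(dist(frame)),
                 tolerance = 1e-10)
  }
})

test_that("meta-trajectory concatenates, superposes, and records provenance", {
  toy <- build_toy_dimer(12, seed = 9)
  springs <- build_spring_graph(toy$structure)
  spec <- ensemble_spec(n_replicas = 3, n_frames = 40, seed = 5)
  trajs <- sample_gnm_trajectory(toy$structure, springs, spec)
  meta <- build_meta_trajectory(trajs, toy$structure)
  expect_equal(n_frames(meta), 120L)
  # provenance is a bijection onto the retained input frames
  key <- paste(meta$provenance$replica, meta$provenance$source_index)
  expect_equal(sort(key),
               sort(paste(rep(1:3, each = 40), rep(1:40, times = 3))))
  # every frame transformed: frame 1 equals the reference on the selection
  sel <- meta$superposition$selection
  expect_equal(meta$xyz[sel, , 1], trajs[[1]]$xyz[sel, , 1],
               tolerance = 1e-10)
  # single replica works
  one <- build_meta_trajectory(trajs[1], toy$structure)
  expect_equal(n_frames(one), 40L)
  # atom-count mismatch rejected
  bad <- trajs
  bad[[2]]$xyz <- bad[[2]]$xyz[-1, , , drop = FALSE]
  expect_error(build_meta_trajectory(bad, toy$structure), "mismatch")
})

test_that("DCD and multi-model PDB round-trip trajectories", {
  toy <- build_toy_dimer(10, seed = 3)
  spec <- ensemble_spec(n_replicas = 1, n_frames = 7, seed = 2)
  tr <- sample_gnm_trajectory(toy$structure, build_spring_graph(toy$structure),
                              spec)[[1]]
  p <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(tr, p)
  back <- read_dcd(p, spacing_ps = tr$spacing_ps)
  expect_equal(dim(back$xyz), dim(tr$xyz))
  expect_equal(back$xyz, tr$xyz, tolerance = 1e-5)   # float32 storage
})
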