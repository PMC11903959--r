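# Toy dimer construction, Gaussian-network sampling, spring perturbation
# and fixture round trips.

test_that("build_toy_dimer is deterministic and validates domains", {
  toy <- build_toy_dimer(50, seed = 21)
  expect_equal(n_residues(toy$structure), 100L)
  expect_setequal(unique(toy$structure$atoms$chain), c("A", "B"))
  toy2 <- build_toy_dimer(50, seed = 21)
  expect_identical(coords(toy$structure), coords(toy2$structure))
  toy3 <- build_toy_dimer(50, seed = 22)
  expect_false(identical(coords(toy$structure), coords(toy3$structure)))
  expect_error(build_toy_dimer(50, domains = list(NTD = c(1, 20),
                                                  CTD = c(25, 50))),
               "contiguous")
  expect_error(build_toy_dimer(50, domains = list(NTD = c(1, 20),
                                                  CTD = c(21, 40))),
               "cover the full span")
  expect_error(build_toy_dimer(5), ">= 10")
  # default geometry keeps non-adjacent residues apart: the 5 A gate is
  # meaningful (adjacent CA ~3.8 A, everything else predominantly > 5 A)
  ca <- coords(toy$structure)[ca_indices(toy$structure), ]
  d <- as.matrix(dist(ca))
  seq_adjacent <- abs(outer(1:100, 1:100, "-")) <= 1
  expect_gt(mean(d[!seq_adjacent] > 5), 0.95)
})

test_that("gnm sampling is seed-deterministic and respects stiffness", {
  toy <- build_toy_dimer(12, seed = 8)
  springs <- build_spring_graph(toy$structure)
  spec <- ensemble_spec(n_replicas = 2, n_frames = 50, seed = 77)
  a <- sample_gnm_trajectory(toy$structure, springs, spec)
  b <- sample_gnm_trajectory(toy$structure, springs, spec)
  expect_identical(a[[1]]$xyz, b[[1]]$xyz)
  expect_identical(a[[2]]$xyz, b[[2]]$xyz)
  expect_false(identical(a[[1]]$xyz, a[[2]]$xyz))  # replicas independent
  # infinite-stiffness limit: distance fluctuations vanish
  stiff <- spring_graph(springs$kmat * 1e6, toy$structure)
  tr <- sample_gnm_trajectory(toy$structure, stiff,
                              ensemble_spec(1, 200, seed = 3))[[1]]
  meta <- make_meta(toy$structure, tr$xyz)
  dfres <- compute_df(meta)
  expect_lt(max(dfres$df), 1e-3)
})

test_that("sampled per-site variance matches the Kirchhoff pseudo-inverse", {
  toy <- build_toy_dimer(10, seed = 5)
  springs <- build_spring_graph(toy$structure)
  kirch <- diag(rowSums(springs$kmat)) - springs$kmat
  eig <- eigen(kirch, symmetric = TRUE)
  live <- eig$values > max(eig$values) * 1e-9
  pinv_diag <- rowSums(sweep(eig$vectors[, live]^2, 2,
                             eig$values[live], "/"))
  tf <- 0.8
  tr <- sample_gnm_trajectory(
    toy$structure, springs,
    ensemble_spec(1, 20000, temperature_factor = tf, seed = 12))[[1]]
  ca <- ca_indices(toy$structure)
  for (ax in 1:3) {
    v <- apply(tr$xyz[ca, ax, ], 1, var)
    expect_equal(v, tf * pinv_diag, tolerance = 0.05)
  }
})

test_that("perturb_springs scales only the incident couplings", {
  toy <- build_toy_dimer(12, seed = 6)
  springs <- build_spring_graph(toy$structure)
  same <- perturb_springs(springs, c("A", 6L), 1)
  expect_identical(same$kmat, springs$kmat)
  weak <- perturb_springs(springs, c("A", 6L), 0.25)
  i <- residue_serial(toy$structure, "A", 6L)
  expect_equal(weak$kmat[i, ], springs$kmat[i, ] * 0.25)
  expect_equal(weak$kmat[-i, -i], springs$kmat[-i, -i])
  expect_error(perturb_springs(springs, c("C", 1L), 0.5), "unknown position")
  # factor 0 isolates the site; sampling then rejects the graph
  iso <- perturb_springs(springs, c("A", 6L), 0)
  expect_error(
    sample_gnm_trajectory(toy$structure, iso,
                          ensemble_spec(1, 10, seed = 1)),
    "disconnected")
})

test_that("weakening a hub increases DF between the site and neighbours", {
  toy <- build_toy_dimer(12, seed = 31)
  springs <- build_spring_graph(toy$structure)
  i <- residue_serial(toy$structure, "A", 6L)
  nb <- which(springs$kmat[i, ] > 0)
  df_for <- function(spr, seed) {
    tr <- sample_gnm_trajectory(toy$structure, spr,
                                ensemble_spec(1, 2000, seed = seed))[[1]]
    compute_df(make_meta(toy$structure, tr$xyz))$df
  }
  df_wt <- df_for(springs, 41)
  df_mut <- df_for(perturb_springs(springs, c("A", 6L), 0.2), 42)
  expect_gt(mean(df_mut[i, nb]), mean(df_wt[i, nb]))
})

test_that("two stiff, barely coupled clusters show the rigid-cluster signature", {
  # 10 residues per cluster spread over > 5 A.  The clusters are internally
  # stiff and joined by one negligible spring: with translational zero
  # modes excluded per connected component, *fully* uncoupled clusters
  # would have no relative motion at all, so "mutually uncoupled" is
  # realized as a bridge 5000x weaker than the intra-cluster couplings.
  set.seed(19)
  base <- cbind(seq(0, 27, length.out = 10), rnorm(10, sd = 0.5),
                rnorm(10, sd = 0.5))
  xyz <- rbind(base, sweep(base, 2, c(0, 40, 0), "+"))
  s <- ca_structure(xyz, chain = rep(c("A", "B"), each = 10))
  kmat <- matrix(0, 20, 20)
  kmat[1:10, 1:10] <- 50; kmat[11:20, 11:20] <- 50
  kmat[10, 11] <- kmat[11, 10] <- 0.01
  diag(kmat) <- 0
  springs <- spring_graph(kmat, s)
  tr <- sample_gnm_trajectory(s, springs,
                              ensemble_spec(1, 3000, seed = 23))[[1]]
  dfres <- compute_df(make_meta(s, tr$xyz))
  intra <- rbind(cbind(rep(1:10, each = 10), rep(1:10, 10)),
                 cbind(rep(11:20, each = 10), rep(11:20, 10)))
  intra <- intra[intra[, 1] != intra[, 2], ]
  inter <- cbind(rep(1:10, each = 10), rep(11:20, 10))
  expect_gt(mean(dfres$df[inter]) / mean(dfres$df[intra]), 10)
  # eta via brute force: only same-cluster residues beyond the gate count
  lf <- local_fluctuation_threshold(dfres$df)
  eta <- connectivity_profile(dfres$df, dfres$mean_dist, lf$LF)
  oracle <- oracle_eta(unclass(dfres$df), unclass(dfres$mean_dist), lf$LF)
  expect_equal(eta$eta, oracle)
  conn <- (unclass(dfres$mean_dist) > 5) & (unclass(dfres$df) < lf$LF)
  diag(conn) <- FALSE
  expect_equal(sum(conn[inter]), 0L)  # flexible far pairs contribute 0
})

test_that("write_fixture round-trips topology and trajectories", {
  toy <- build_toy_dimer(10, seed = 14)
  spec <- ensemble_spec(n_replicas = 3, n_frames = 5, seed = 4)
  trajs <- sample_gnm_trajectory(toy$structure,
                                 build_spring_graph(toy$structure), spec)
  dir <- withr::local_tempdir()
  files <- write_fixture(toy$structure, toy$topology, trajs, dir,
                         params = list(seed = 4))
  expect_length(grep("rep[0-9]+\\.dcd$", files), 3L)
  back <- load_structure(file.path(dir, "topology.pdb"))
  expect_equal(nrow(back$atoms), nrow(toy$structure$atoms))
  expect_equal(unique(back$axis$chain), unique(toy$structure$axis$chain))
  expect_equal(coords(back), coords(toy$structure), tolerance = 1e-3)
  tr2 <- read_dcd(file.path(dir, "rep2.dcd"))
  expect_equal(tr2$xyz, trajs[[2]]$xyz, tolerance = 1e-5)
  # determinism: identical spec => byte-identical text outputs
  dir2 <- withr::local_tempdir()
  trajs_b <- sample_gnm_trajectory(toy$structure,
                                   build_spring_graph(toy$structure), spec)
  write_fixture(toy$structure, toy$topology, trajs_b, dir2,
                params = list(seed = 4))
  for (f in c("topology.pdb", "topology.json", "manifest.json"))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})
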