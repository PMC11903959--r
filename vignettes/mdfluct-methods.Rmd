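---
title: "mdfluct: methods, parameter choices and validation limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mdfluct: methods, parameter choices and validation limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mdfluct)
```

## The model

The package treats an MD ensemble as an exchangeable set of coordinate
frames and asks one question of every residue pair (i, j): how variable
is their Cα–Cα distance?  The distance-fluctuation score

$$DF_{ij} = \langle (d_{ij} - \langle d_{ij}\rangle)^2 \rangle$$

is the *population* variance of that distance over the frames.  Pairs
with small DF move quasi-rigidly regardless of how far apart they are —
which is exactly what makes DF useful for allostery: a distal pair with
small DF is mechanically coupled through the structure.  Three derived
quantities make this operational:

* **LF (local fluctuation)** — for residue i, the mean of $DF_{ij}$ over
  the sequence neighbours $j = i \pm 2$ in the same chain, clipped at
  chain termini; the protein-wide mean of the $LF_i$ is the single
  threshold LF.  Sequence neighbours are covalently tethered, so their
  DF sets the natural scale of "as coordinated as it gets".
* **η (mechanical connectivity)** — the number of residues j with mean
  distance $\langle d_{ij}\rangle$ *strictly greater* than 5 Å and
  $DF_{ij}$ *strictly below* LF.  The 5 Å gate removes trivial contact
  neighbours; what remains is genuinely long-range coordination.  Pairs
  may span the two protomers.
* **Δη and %ΔDF** — mutant-minus-wild-type differences.  %ΔDF is
  $100\,(DF^{mut}-DF^{WT})/DF^{WT}$, masked (NA, exported as empty
  fields) wherever $DF^{WT}$ is below a floor of $10^{-6}$ Å², including
  the diagonal, so near-rigid reference pairs never produce infinities.
  The column of %ΔDF at a mutated position is the P_mut projection.

### Conventions that required a decision

* **LF window.** "Neighbours at i ± 2" can be read as the inclusive
  window {i−2, i−1, i+1, i+2} or as exactly the two residues at ±2.
  The inclusive window is the default (`mode = "inclusive"`), because
  covalent neighbours at ±1 are the strongest expression of local
  tethering; the strict reading remains available (`mode = "exact"`).
* **Strict inequalities** on both gates (> 5 Å, < LF).  A fully rigid
  synthetic system (DF ≡ 0, LF = 0) therefore has η ≡ 0 rather than
  everything connected — the degenerate case resolves conservatively.
* **One scalar LF per system**, not per residue, and each system
  (wild type, mutant) uses *its own* LF.  This has a consequence worth
  understanding: weakening the couplings around one site raises that
  system's global LF slightly, which can *raise* η of residues whose DF
  pattern did not change.  The reliable local signature of a
  destabilizing perturbation is therefore the drop of η *at the
  perturbed site* (large and systematic in our recovery experiments:
  Δη between −11 and −18 in 20/20 seeded replicates at default scales)
  together with the positive P_mut over its contact cluster; the mean
  Δη over the cluster is not sign-stable and is not used as a criterion.
* **Population (1/M) variance**, not 1/(M−1): at M = 12,000 frames the
  difference is far below any interpretable signal, and the fixed
  convention makes brute-force oracle comparisons exact.

## Frame handling

A production replica saved every 10 ps for 300 ns yields 30,000 frames.
Equilibration trimming keeps frames with timestamp *strictly greater*
than the discard time, then every k-th frame starting from the first
retained; discarding 100 ns with stride 5 gives exactly 4,000 frames at
50 ps, and three replicas concatenate to a 12,000-frame meta-trajectory
covering 600 ns.  The strict-inequality boundary was chosen because it
reproduces these printed counts exactly.

Every frame is superposed (optimal least-squares rigid fit, Kabsch SVD
with the determinant correction) onto the first frame of the first
replica.  The fit selection is the backbone (N, Cα, C, O) of residues
assigned helix or strand in that reference frame, computed once and
frozen — the reference is a single fixed frame, so recomputing the
selection per frame would change the meaning of the alignment.  Which
secondary-structure classes "count" is not specified anywhere
authoritative; helix + strand (H, G, I, E, B) is used.  Coarse synthetic
systems may have no helix/strand residues at all, in which case the
selection falls back to the full backbone (and then to all Cα).  Note
that DF itself is superposition-invariant (distances are unchanged by
rigid motions — this is tested to 1e-8 Å²); superposition matters only
for RMSF and for visual outputs.

## The synthetic generator: what it emulates, what it does not

`build_toy_dimer()` lays out two identical serpentine Cα folds (3.8 Å
between consecutive residues, wider row/layer spacing so non-adjacent
residues are predominantly > 5 Å apart — making the distance gate
meaningful), adds minimal backbone N, H, C, O atoms, and places the
second chain with an ~8 Å interface gap so the default 10 Å spring
cutoff creates inter-protomer couplings.

`sample_gnm_trajectory()` draws frames as the mean structure plus
Gaussian displacements whose per-Cartesian-component covariance is the
temperature factor times the Moore–Penrose pseudo-inverse of the
weighted Kirchhoff matrix — the classic Gaussian-network model.  Three
deliberate simplifications:

* **Frames are independent draws** with no temporal correlation.  DF,
  RMSF, occupancy and SS frequencies are time-order-invariant
  statistics, so autocorrelation adds nothing to their validation; frame
  count is purely a sampling-precision knob.  Consequently test and demo
  ensembles use hundreds of frames where production protocols use tens
  of thousands, keeping the whole suite inside its time budget.
* **Isotropic per-component covariance** (GNM, not ANM): the closed-form
  covariance gives an analytic oracle (sampled per-site variance matches
  the pseudo-inverse diagonal within 5% at 20,000 frames).
* **Residues displace rigidly** (all atoms of a residue share the Cα
  displacement), so internal residue geometry — and hence static SS and
  H-bond geometry — is preserved by construction.

Rigid translational zero modes are excluded per connected component.
This has a subtle consequence: two *completely* uncoupled stiff clusters
have no relative motion at all (their rigid-body modes are exactly the
excluded zero modes), so the "rigid clusters ⇒ huge inter-cluster DF"
signature is realized with a bridge spring thousands of times weaker
than the intra-cluster couplings; the observed inter/intra DF ratio is
then ~10⁴, far above the required 10.

"Mutations" are `perturb_springs()` calls scaling all couplings incident
to one site; factor 0 isolates the site and is rejected downstream as a
disconnected graph.

A green synthetic test therefore establishes that the *estimators* are
correct and that the analysis recovers *known* coordination structure;
it says nothing about force-field realism, solvent effects, sampling
convergence of real trajectories, or the specific published profiles of
any real system, which depend on undeposited microsecond-scale
production data.

## Per-residue descriptors

* **RMSF** uses the arithmetic mean structure of the superposed
  meta-trajectory as reference and averages squared deviations over
  backbone atoms per residue.  Closed-form check: isotropic noise of
  per-component σ gives RMSF = σ√3 (within 3% at 10,000 frames).
* **H-bonds**: a donor–H⋯acceptor triple is bonded when the
  donor-heavy-atom→acceptor distance ≤ 3.0 Å and the donor–H–acceptor
  angle ≥ 135° — the conventional defaults of MD post-processing tools;
  the hydrogen→acceptor distance variant is available by flag.  Donors
  are N/O with a hydrogen within 1.25 Å in the reference geometry;
  missing hydrogens are a configuration error, not a silent zero.
* **Secondary structure** follows the Kabsch–Sander scheme: backbone
  H-bond energy $E = 27.888\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} -
  1/r_{CN}$) kcal/mol, bonded when E < −0.5; amide H reconstructed 1 Å
  from N along the preceding C=O direction when not explicit;
  n→n+4/3/5 turn pairs make H/G/I helices, bridges make E (ladder) or B
  (isolated), lone turns T, Cα bends over 70° S; priority
  H > E/B > G > I > T > S.  The implementation reproduces an independent
  Kabsch–Sander implementation exactly on ideal poly-Ala helix and
  strand geometries (assignment strings frozen in the tests).  Reports
  keep all eight classes so that pooled "helix" conventions (H+G or
  H+G+I) can be applied downstream without re-assignment.
* **SASA** is Shrake–Rupley with 960 golden-spiral points per atom
  (≤ 1% sampling error on the closed-form isolated-atom case) and probe
  1.4 Å; relative SASA divides by the Tien et al. (2013) theoretical
  Gly-X-Gly maxima, clamped to [0, 1].  Published relative-SASA figures
  from other pipelines may use different maxima tables, so agreement is
  claimed only against an independent Shrake–Rupley implementation
  (within 2% on a test tripeptide), not against any printed percentage.

## Numerical choices

* DF accumulates a Welford running mean/M2 per pair in a single
  streaming pass over frames: memory is O(N²) regardless of frame
  count (N ≈ 1300, M ≈ 12,000 fits comfortably), and cancellation-free
  variances match two-pass oracles to ≤ 1e-9 relative even for
  near-rigid pairs.
* Superposition uses SVD with the sign correction that excludes
  reflections; selections of fewer than 3 atoms are rejected as
  underdetermined.
* Replica seeds derive deterministically from the ensemble seed
  (`seed + 10007·replica`, kept below 2³¹); identical specs reproduce
  byte-identical fixtures and pipeline outputs (manifest checksums are
  compared in the tests).
* B-factor export uses the fixed `%6.2f` field; values beyond ±999.99
  are an explicit error suggesting a rescale, masked residues write 0.00
  and are listed in a sidecar file.

## Known limitations

* PDB parsing rejects insertion codes and alternate locations rather
  than resolving them; upstream preparation is assumed.
* Trajectory input is multi-model PDB or CHARMM/NAMD DCD; XTC is not
  supported (no compression codec dependency was worth carrying for this
  scope).  Periodic-boundary re-imaging is out of scope; inputs are
  assumed imaged and solvent-stripped.
* The bridge/ladder logic of the SS assignment is deliberately minimal
  (no ladder direction bookkeeping, no β-bulges); it is validated on
  ideal geometries, not against full DSSP on irregular folds.
* Configs are JSON rather than YAML (no YAML parser in the dependency
  budget).
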