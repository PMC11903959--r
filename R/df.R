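#' Distance-fluctuation and mean-distance matrices of a meta-trajectory
#'
#' For every Calpha pair (i, j) across both protomers, computes
#' `DF_ij = < (d_ij - <d_ij>)^2 >`, the population variance over frames of
#' the Euclidean i-j distance (A^2), and `<d_ij>`, its frame average (A).
#' Small DF marks mechanically coordinated pairs moving quasi-rigidly;
#' large DF marks uncoordinated motion.  A single streaming pass keeps a
#' Welford running mean and squared-deviation accumulator per pair, so
#' frame count limits neither memory nor precision.
#'
#' @param meta a `MetaTrajectory` (or `Trajectory` plus `structure`)
#' @param structure optional `StructureModel` when `meta` is a plain
#'   `Trajectory`
#' @return list with `df` (class `DFMatrix`) and `mean_dist` (class
#'   `MeanDistanceMatrix`); both carry the residue axis map in
#'   `attr(, "axis")`.
#' @export
compute_df <- function(meta, structure = NULL) {
  if (inherits(meta, "MetaTrajectory")) structure <- meta$structure
  if (is.null(structure)) stop("structure required for a plain Trajectory")
  m <- n_frames(meta)
  if (m < 2L)
    stop("insufficient data: need at least 2 frames to compute variances")
  ca <- ca_indices(structure)
  n <- length(ca)
  # Welford running mean / M2 per pair: single pass, numerically stable
  mean_d <- matrix(0, n, n)
  m2 <- matrix(0, n, n)
  for (f in seq_len(m)) {
    d <- unname(as.matrix(dist(meta$xyz[ca, , f])))
    delta <- d - mean_d
    mean_d <- mean_d + delta / f
    m2 <- m2 + delta * (d - mean_d)
  }
  dfm <- m2 / m              # population variance
  dfm[dfm < 0] <- 0          # guard tiny negative round-off
  diag(dfm) <- 0; diag(mean_d) <- 0
  axis <- structure$axis[, c("serial", "chain", "resid")]
  attr(dfm, "axis") <- axis; attr(mean_d, "axis") <- axis
  class(dfm) <- c("DFMatrix", class(dfm))
  class(mean_d) <- c("MeanDistanceMatrix", class(mean_d))
  list(df = dfm, mean_dist = mean_d)
}

check_same_axis <- function(a, b) {
  ax <- attr(a, "axis"); bx <- attr(b, "axis")
  if (is.null(ax) || is.null(bx) || !identical(ax$chain, bx$chain) ||
      !identical(ax$resid, bx$resid))
    stop("axis maps do not match between matrices")
  ax
}

#' Local-fluctuation threshold
#'
#' The local fluctuation of residue i, `LF_i`, averages `DF_ij` over the
#' close sequence neighbours j = i +/- 2 within the same chain, clipped at
#' chain termini; the protein-wide threshold `LF` is the mean of `LF_i`
#' over all residues.  Pairs below this threshold count as mechanically
#' connected.
#'
#' @param df a `DFMatrix`
#' @param mode `"inclusive"` (default) uses the window
#'   \{i-2, i-1, i+1, i+2\}; `"exact"` uses only i-2 and i+2.
#' @return list with scalar `LF` and vector `LF_i`
#' @export
local_fluctuation_threshold <- function(df, mode = c("inclusive", "exact")) {
  mode <- match.arg(mode)
  axis <- attr(df, "axis")
  if (is.null(axis)) stop("DF matrix lacks its axis map")
  n <- nrow(df)
  offsets <- if (mode == "inclusive") c(-2L, -1L, 1L, 2L) else c(-2L, 2L)
  lf_i <- numeric(n)
  for (ch in unique(axis$chain)) {
    idx <- which(axis$chain == ch)
    if (length(idx) < 3L)
      stop("chain ", ch, " shorter than 3 residues; LF undefined")
    for (p in seq_along(idx)) {
      nb <- p + offsets
      nb <- nb[nb >= 1L & nb <= length(idx)]
      lf_i[idx[p]] <- mean(df[idx[p], idx[nb]])
    }
  }
  list(LF = mean(lf_i), LF_i = lf_i)
}

#' Per-residue mechanical connectivity
#'
#' `eta_i` counts the residues j (either protomer) whose mean distance to
#' i exceeds the gate (strictly) while their DF score is strictly below
#' the LF threshold: distal residues moving quasi-rigidly with i.
#'
#' @param df a `DFMatrix`
#' @param dist a `MeanDistanceMatrix` on the same axis
#' @param lf scalar threshold, normally `local_fluctuation_threshold()$LF`
#' @param gate mean-distance gate in Angstrom (default 5)
#' @return A `ConnectivityProfile`: data.frame with chain, resid, eta,
#'   plus the threshold and gate as attributes.
#' @export
connectivity_profile <- function(df, dist, lf, gate = 5) {
  axis <- check_same_axis(df, dist)
  connected <- (dist > gate) & (unclass(df) < lf)
  diag(connected) <- FALSE
  eta <- as.integer(rowSums(connected))
  out <- data.frame(chain = axis$chain, resid = axis$resid, eta = eta)
  attr(out, "LF") <- lf
  attr(out, "gate") <- gate
  attr(out, "axis") <- axis
  class(out) <- c("ConnectivityProfile", class(out))
  out
}

#' Connectivity change upon mutation
#'
#' `delta_eta_i = eta_mut,i - eta_WT,i`; positive values mark residues
#' gaining mechanical coordination in the mutant, negative values mark
#' loss.  Each profile must have been computed with its own system's LF
#' threshold.
#'
#' @param mut mutant `ConnectivityProfile`
#' @param wt wild-type `ConnectivityProfile`
#' @return A per-residue track (data.frame chain, resid, value) labelled
#'   `delta_eta`.
#' @export
delta_connectivity <- function(mut, wt) {
  if (!identical(mut$chain, wt$chain) || !identical(mut$resid, wt$resid))
    stop("axis maps do not match between profiles")
  track <- data.frame(chain = mut$chain, resid = mut$resid,
                      value = mut$eta - wt$eta)
  attr(track, "label") <- "delta_eta"
  class(track) <- c("PerResidueScalar", class(track))
  track
}

#' Percentage DF difference matrix (mutant vs wild type)
#'
#' `100 * (DF_mut - DF_WT) / DF_WT` wherever `DF_WT` is at least `floor`;
#' entries with near-zero wild-type DF (including the diagonal) are
#' masked as NA rather than producing infinities.  Positive entries mark
#' pairs losing mechanical coordination upon mutation, negative entries
#' pairs gaining it.
#'
#' @param mut mutant `DFMatrix`
#' @param wt wild-type `DFMatrix` on the same axis
#' @param floor smallest `DF_WT` (A^2) considered defined (default 1e-6)
#' @return A `DiffMatrix` (percent) with masked entries NA.
#' @export
percent_delta_df <- function(mut, wt, floor = 1e-6) {
  axis <- check_same_axis(mut, wt)
  out <- matrix(NA_real_, nrow(wt), ncol(wt))
  ok <- unclass(wt) >= floor
  out[ok] <- 100 * (unclass(mut)[ok] - unclass(wt)[ok]) / unclass(wt)[ok]
  attr(out, "axis") <- axis
  attr(out, "units") <- "percent"
  class(out) <- c("DiffMatrix", class(out))
  out
}

#' Absolute DF difference matrix
#'
#' `DF_mut - DF_WT` in A^2, unmasked.
#' @param mut mutant `DFMatrix`
#' @param wt wild-type `DFMatrix` on the same axis
#' @export
delta_df <- function(mut, wt) {
  axis <- check_same_axis(mut, wt)
  out <- unclass(mut) - unclass(wt)
  attr(out, "axis") <- axis
  attr(out, "units") <- "A^2"
  class(out) <- c("DiffMatrix", class(out))
  out
}

#' Extract the difference-matrix column at a mutated position
#'
#' The column of the percentage DF difference matrix at a mutated
#' position, mapped over all residues; projecting it onto the structure
#' (e.g. via the B-factor column) shows which residues gain (negative) or
#' lose (positive) coordination with that site.  The track label is
#' `P_mutA` or `P_mutB` according to the position's protomer.
#'
#' @param diff a `DiffMatrix`
#' @param chain chain id of the mutated position
#' @param resid residue number of the mutated position
#' @return A `PerResidueScalar` track; masked entries stay NA.
#' @export
project_column <- function(diff, chain, resid) {
  axis <- attr(diff, "axis")
  i <- which(axis$chain == chain & axis$resid == resid)
  if (length(i) != 1L)
    stop("unknown position ", chain, ":", resid, " in difference matrix")
  track <- data.frame(chain = axis$chain, resid = axis$resid,
                      value = unclass(diff)[, i])
  attr(track, "label") <- paste0("P_mut", chain)
  class(track) <- c("PerResidueScalar", class(track))
  track
}

#' Write a residue-pair matrix as labelled TSV
#'
#' Header row and first column carry `chain:resid` labels; masked entries
#' are exported as empty fields, not zeros.
#'
#' @param mat a matrix with an `axis` attribute
#' @param path output path
#' @export
write_matrix_tsv <- function(mat, path) {
  axis <- attr(mat, "axis")
  labels <- paste0(axis$chain, ":", axis$resid)
  m <- unclass(mat)
  body <- apply(m, 1, function(r)
    paste(ifelse(is.na(r), "", formatC(r, format = "g", digits = 10)),
          collapse = "\t"))
  lines <- c(paste(c("", labels), collapse = "\t"),
             paste(labels, body, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-residue track as TSV with numbering and domain context
#'
#' Columns: chain, resid_model, resid_human, domain, value.
#'
#' @param track a `PerResidueScalar` (data.frame chain, resid, value) or
#'   `ConnectivityProfile` (eta used as value)
#' @param topology a `TopologySpec` for numbering/domain columns
#' @param path output path
#' @export
write_track_tsv <- function(track, topology, path) {
  value <- if ("value" %in% names(track)) track$value else track$eta
  out <- data.frame(chain = track$chain,
                    resid_model = track$resid,
                    resid_human = track$resid - topology$offset,
                    domain = assign_domain(track$resid, topology),
                    value = value)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
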