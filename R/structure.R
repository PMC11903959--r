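#' Structure model: ordered atom records with reference coordinates
#'
#' A `StructureModel` is the topology + reference geometry used throughout
#' the package: an ordered atom table (name, element, residue index,
#' residue name, chain id, coordinates in Angstrom) plus a dense residue
#' serial map.  Residue indices are 1-based PDB numbering; the chain id
#' disambiguates duplicate numbers across protomers.  Internally every
#' residue gets a dense 1-based serial (the "axis") used for matrix axes.
#'
#' @param atoms data.frame with columns `name`, `element`, `resid`
#'   (integer), `resname`, `chain`, `x`, `y`, `z`.
#' @return An object of class `StructureModel`.
#' @export
structure_model <- function(atoms) {
  req <- c("name", "element", "resid", "resname", "chain", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0L)
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms$resid <- as.integer(atoms$resid)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  for (ch in unique(atoms$chain)) {
    r <- atoms$resid[atoms$chain == ch]
    if (is.unsorted(r))  # equal neighbours allowed (atoms of one residue)
      stop("residue indices not increasing within chain ", ch)
  }
  key <- paste(atoms$chain, atoms$resid)
  ukey <- unique(key)
  axis <- data.frame(
    serial  = seq_along(ukey),
    chain   = atoms$chain[match(ukey, key)],
    resid   = atoms$resid[match(ukey, key)],
    resname = atoms$resname[match(ukey, key)],
    stringsAsFactors = FALSE
  )
  ca_row <- vapply(ukey, function(k) {
    rows <- which(key == k & atoms$name == "CA")
    if (length(rows) > 1L)
      stop("residue ", k, " has ", length(rows), " CA atoms")
    if (length(rows) == 0L) NA_integer_ else rows[1L]
  }, integer(1), USE.NAMES = FALSE)
  axis$ca_row <- ca_row
  structure(list(atoms = atoms, axis = axis), class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel:", nrow(x$atoms), "atoms,", nrow(x$axis),
      "residues, chains {", paste(unique(x$axis$chain), collapse = ", "),
      "}\n")
  invisible(x)
}

#' Number of residues in a structure
#' @param structure a `StructureModel`
#' @export
n_residues <- function(structure) nrow(structure$axis)

#' Atom coordinates as an n x 3 matrix
#' @param structure a `StructureModel`
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Row indices of Calpha atoms, one per residue (axis order)
#'
#' Errors if any residue lacks a Calpha, since every residue used by the
#' distance-fluctuation analysis must have exactly one.
#' @param structure a `StructureModel`
#' @export
ca_indices <- function(structure) {
  rows <- structure$axis$ca_row
  if (anyNA(rows)) {
    bad <- structure$axis[is.na(rows), ]
    stop("missing CA atom in residue(s): ",
         paste(paste0(bad$chain, ":", bad$resid), collapse = ", "))
  }
  rows
}

#' Row indices of backbone heavy atoms (N, CA, C, O)
#' @param structure a `StructureModel`
#' @param residues optional integer vector of residue serials to restrict to
#' @export
backbone_indices <- function(structure, residues = NULL) {
  at <- structure$atoms
  sel <- at$name %in% c("N", "CA", "C", "O")
  if (!is.null(residues)) {
    key <- paste(at$chain, at$resid)
    keep <- paste(structure$axis$chain, structure$axis$resid)[residues]
    sel <- sel & key %in% keep
  }
  which(sel)
}

#' Resolve a (chain, resid) pair to its dense residue serial
#' @param structure a `StructureModel`
#' @param chain chain identifier
#' @param resid residue number (PDB numbering)
#' @export
residue_serial <- function(structure, chain, resid) {
  i <- which(structure$axis$chain == chain & structure$axis$resid == resid)
  if (length(i) != 1L)
    stop("unknown residue ", chain, ":", resid)
  i
}

# ---------------------------------------------------------------------------
# PDB I/O.  Fixed-column format per the wwPDB spec; only ATOM records are
# read.  Insertion codes and alternate locations are rejected: upstream
# preparation is expected to have resolved them.

parse_pdb_atom <- function(line, lineno) {
  if (nchar(line) < 54)
    stop("malformed ATOM record at line ", lineno, " (truncated)")
  xyz <- suppressWarnings(as.numeric(c(
    substr(line, 31, 38), substr(line, 39, 46), substr(line, 47, 54))))
  if (anyNA(xyz))
    stop("malformed ATOM record at line ", lineno, " (bad coordinates)")
  resid <- suppressWarnings(as.integer(trimws(substr(line, 23, 26))))
  if (is.na(resid))
    stop("malformed ATOM record at line ", lineno, " (bad residue number)")
  altloc <- substr(line, 17, 17)
  if (altloc != " ")
    stop("alternate location '", altloc, "' at line ", lineno,
         " not supported; keep a single conformer upstream")
  icode <- substr(line, 27, 27)
  if (icode != " ")
    stop("insertion code '", icode, "' at line ", lineno, " not supported")
  elem <- trimws(substr(line, 77, 78))
  name <- trimws(substr(line, 13, 16))
  if (elem == "") elem <- substr(gsub("[0-9]", "", name), 1, 1)
  list(name = name, element = elem,
       resname = trimws(substr(line, 18, 20)),
       chain = substr(line, 22, 22), resid = resid,
       x = xyz[1], y = xyz[2], z = xyz[3],
       bfactor = suppressWarnings(as.numeric(substr(line, 61, 66))))
}

#' Read a PDB file into a StructureModel
#'
#' Parses ATOM records of the first MODEL (or the whole file when no MODEL
#' cards are present).  HETATM, solvent and ions are skipped.  Alternate
#' locations and insertion codes raise an error.
#'
#' @param path path to a PDB file
#' @return A `StructureModel`; atom B-factors are kept in column `bfactor`.
#' @export
load_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- list(); inmodel <- TRUE
  for (i in seq_along(lines)) {
    tag <- substr(lines[[i]], 1, 6)
    if (tag == "MODEL ") inmodel <- length(recs) == 0L
    if (tag == "ENDMDL" && length(recs) > 0L) break
    if (tag == "ATOM  " && inmodel)
      recs[[length(recs) + 1L]] <- parse_pdb_atom(lines[[i]], i)
  }
  if (length(recs) == 0L) stop("no ATOM records in ", path)
  atoms <- do.call(rbind, lapply(recs, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  structure_model(atoms)
}

format_pdb_atom <- function(i, name, resname, chain, resid, x, y, z, b, elem) {
  # atom names: columns 13-16, right-packed for 1-3 char names per PDB rules
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else paste0(" ", name)
  sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i %% 100000, nm, resname, chain, resid, x, y, z, 1.00, b, elem)
}

#' Write a StructureModel to a PDB file
#'
#' @param structure a `StructureModel`
#' @param path output path
#' @param bfactor per-atom numeric vector for the B-factor column
#'   (default 0); values must fit the fixed-width `%6.2f` field.
#' @export
write_pdb <- function(structure, path, bfactor = NULL) {
  at <- structure$atoms
  if (is.null(bfactor)) bfactor <- rep(0, nrow(at))
  if (any(abs(bfactor) > 999.99))
    stop("B-factor magnitude exceeds 999.99; rescale the track before writing")
  lines <- character(nrow(at) + 1L)
  chain_prev <- NULL
  for (i in seq_len(nrow(at))) {
    lines[i] <- format_pdb_atom(i, at$name[i], at$resname[i], at$chain[i],
                                at$resid[i], at$x[i], at$y[i], at$z[i],
                                bfactor[i], at$element[i])
  }
  lines[length(lines)] <- "END"
  writeLines(lines, path)
  invisible(path)
}
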