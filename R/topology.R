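#' Topology specification: protomers, numbering offset, domains, mutations
#'
#' Encodes the semantic layer on top of the raw structure: which chain is
#' which protomer, the constant offset between model numbering and the
#' reference (e.g. human) numbering, the domain ranges in model numbering,
#' and the mutated position(s).  For the zebrafish Trap1 structure the
#' offset is 15 (model minus human) and the canonical domain ranges are
#' NTD 85-310, LMD 311-470, SMD 471-586, CTD 587-719.
#'
#' @param chains named character vector mapping chain id to protomer label,
#'   e.g. `c(A = "A", B = "B")`.
#' @param offset integer; model numbering minus reference numbering.
#' @param domains named list of length-2 integer vectors `c(first, last)`
#'   in model numbering; ranges must be contiguous and non-overlapping.
#' @param mutations integer vector of mutated positions in model numbering
#'   (applies to both protomers).
#' @return An object of class `TopologySpec`.
#' @export
topology_spec <- function(chains = c(A = "A", B = "B"),
                          offset = 15L,
                          domains = list(NTD = c(85L, 310L),
                                         LMD = c(311L, 470L),
                                         SMD = c(471L, 586L),
                                         CTD = c(587L, 719L)),
                          mutations = integer()) {
  if (is.null(names(chains)) || any(names(chains) == ""))
    stop("chains must be a named vector: chain id -> protomer label")
  dm <- do.call(rbind, lapply(domains, function(d) as.integer(d)))
  if (is.null(dm) || ncol(dm) != 2L || any(dm[, 1] > dm[, 2]))
    stop("each domain must be c(first, last) with first <= last")
  ord <- order(dm[, 1])
  dm <- dm[ord, , drop = FALSE]
  if (nrow(dm) > 1L) {
    gaps <- dm[-1L, 1] - dm[-nrow(dm), 2]
    if (any(gaps != 1L))
      stop("domain ranges must be contiguous and non-overlapping ",
           "within the protomer span")
  }
  span <- c(dm[1L, 1], dm[nrow(dm), 2])
  mutations <- as.integer(mutations)
  if (length(mutations) > 0L &&
      any(mutations < span[1] | mutations > span[2]))
    stop("mutated position(s) outside declared domain ranges: ",
         paste(mutations[mutations < span[1] | mutations > span[2]],
               collapse = ", "))
  domains <- lapply(domains, function(d) as.integer(d)[1:2])
  structure(list(chains = chains, offset = as.integer(offset),
                 domains = domains[names(domains)[ord]], span = span,
                 mutations = mutations),
            class = "TopologySpec")
}

#' @export
print.TopologySpec <- function(x, ...) {
  cat("TopologySpec: chains {",
      paste(names(x$chains), "->", x$chains, collapse = ", "),
      "}, offset", x$offset, "\n  domains:",
      paste(sprintf("%s %d-%d", names(x$domains),
                    vapply(x$domains, `[`, integer(1), 1L),
                    vapply(x$domains, `[`, integer(1), 2L)),
            collapse = ", "), "\n")
  if (length(x$mutations))
    cat("  mutated position(s):", paste(x$mutations, collapse = ", "), "\n")
  invisible(x)
}

#' Map residue numbers between model and reference numbering
#'
#' Model numbering minus the topology offset gives reference (human)
#' numbering; the reverse direction adds it.  The round trip is the
#' identity.
#'
#' @param position residue index (scalar or vector)
#' @param direction `"model_to_human"` or `"human_to_model"`
#' @param topology a `TopologySpec`
#' @return mapped residue index (integer)
#' @export
map_numbering <- function(position,
                          direction = c("model_to_human", "human_to_model"),
                          topology) {
  direction <- match.arg(direction)
  position <- as.integer(position)
  model_pos <- if (direction == "model_to_human") position
               else position + topology$offset
  out_of_span <- model_pos < topology$span[1] | model_pos > topology$span[2]
  if (any(out_of_span))
    stop("position(s) outside topology span [", topology$span[1], ", ",
         topology$span[2], "] in model numbering: ",
         paste(position[out_of_span], collapse = ", "))
  if (direction == "model_to_human") position - topology$offset
  else model_pos
}

#' Domain label of a residue position
#'
#' @param position residue index in model numbering (scalar or vector)
#' @param topology a `TopologySpec`
#' @return character vector of domain labels
#' @export
assign_domain <- function(position, topology) {
  position <- as.integer(position)
  out <- rep(NA_character_, length(position))
  for (nm in names(topology$domains)) {
    d <- topology$domains[[nm]]
    out[position >= d[1] & position <= d[2]] <- nm
  }
  if (anyNA(out))
    stop("position(s) outside all domain ranges: ",
         paste(position[is.na(out)], collapse = ", "))
  out
}

#' Read a TopologySpec from a JSON config file
#'
#' Schema: `{"chains": {"A": "A", "B": "B"}, "offset": 15,
#' "domains": {"NTD": [85, 310], ...}, "mutations": [615]}`.
#'
#' @param path path to JSON file
#' @export
read_topology_spec <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  topology_spec(chains = unlist(cfg$chains),
                offset = cfg$offset,
                domains = lapply(cfg$domains, as.integer),
                mutations = if (is.null(cfg$mutations)) integer()
                            else cfg$mutations)
}

#' Write a TopologySpec to a JSON config file
#' @param topology a `TopologySpec`
#' @param path output path
#' @export
write_topology_spec <- function(topology, path) {
  jsonlite::write_json(
    list(chains = as.list(topology$chains),
         offset = topology$offset,
         domains = topology$domains,
         mutations = topology$mutations),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
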