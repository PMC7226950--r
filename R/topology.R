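#' Molecular topology with named region selections
#'
#' A \code{topology} is the static description of a system: one row per atom
#' plus a map of named regions (e.g. \code{"groove"}, \code{"peptide"},
#' \code{"Valpha"}) to ordered atom-id vectors. All coordinates handled by the
#' package are in nanometres; residue numbering is 1-based as in structure
#' files.
#'
#' @param atoms data.frame with columns \code{id} (unique integer),
#'   \code{name} (atom name, e.g. "CA"), \code{element}, \code{resno}
#'   (residue number), \code{resname}, \code{chain}, and optionally
#'   \code{insert} (PDB insertion code), \code{charge} (e), \code{sigma}
#'   (LJ sigma, nm), \code{epsilon} (LJ well depth, kJ/mol).
#' @param region_map named list; each element an integer vector of atom ids.
#' @param pep_labels optional character vector of peptide position labels
#'   (\code{"P1"},\code{"P2"},...) parallel to \code{region_map$peptide}.
#'
#' @return object of class \code{"topology"}.
#' @export
topology <- function(atoms, region_map = list(), pep_labels = NULL) {
  required <- c("id", "name", "element", "resno", "resname", "chain")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(atoms$id))
    stop("atom ids must be unique")
  for (opt in c("insert", "charge", "sigma", "epsilon"))
    if (is.null(atoms[[opt]])) atoms[[opt]] <- rep(NA, nrow(atoms))
  atoms$insert <- as.character(atoms$insert)
  for (rn in names(region_map)) {
    bad <- setdiff(region_map[[rn]], atoms$id)
    if (length(bad))
      stop("region '", rn, "' references unknown atom id(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (!is.null(pep_labels)) {
    pep <- region_map[["peptide"]]
    if (is.null(pep) || length(pep_labels) != length(pep))
      stop("pep_labels must parallel region_map$peptide")
  } else if (!is.null(region_map[["peptide"]])) {
    pep_labels <- paste0("P", seq_along(region_map[["peptide"]]))
  }
  structure(list(atoms = atoms, region_map = region_map,
                 pep_labels = pep_labels),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno, x$atoms$insert))),
      "residues\n")
  if (length(x$region_map))
    cat("regions:", paste(sprintf("%s(%d)", names(x$region_map),
                                  lengths(x$region_map)), collapse = ", "),
        "\n")
  invisible(x)
}

#' Number of atoms in a topology or ensemble
#' @param x a \code{topology} or \code{ensemble}.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "ensemble")) x <- x$topology
  nrow(x$atoms)
}

#' Coordinate ensemble (trajectory) bound to a topology
#'
#' Frames are stored as an \code{N x 3 x T} array in nanometres. Optional
#' per-frame timestamps (ns) must be strictly increasing; optional box
#' vectors are a \code{T x 3} matrix of orthorhombic box lengths (nm).
#'
#' @param topology a \code{topology}.
#' @param coords numeric array \code{N x 3 x T} (a single \code{N x 3}
#'   matrix is promoted to one frame).
#' @param times optional numeric vector of frame times (ns), length T.
#' @param box optional \code{T x 3} matrix (or length-3 vector recycled).
#' @return object of class \code{"ensemble"}.
#' @export
ensemble <- function(topology, coords, times = NULL, box = NULL) {
  stopifnot(inherits(topology, "topology"))
  if (is.matrix(coords)) coords <- array(coords, c(dim(coords), 1L))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("coords must be an N x 3 x T array")
  if (dim(coords)[1] != nrow(topology$atoms))
    stop("frame atom count (", dim(coords)[1],
         ") does not match topology (", nrow(topology$atoms), ")")
  nt <- dim(coords)[3]
  if (!is.null(times)) {
    if (length(times) != nt) stop("times length must equal frame count")
    if (nt > 1L && any(diff(times) <= 0))
      stop("timestamps must be strictly increasing")
  }
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nt, 3, byrow = TRUE)
    if (nrow(box) != nt || ncol(box) != 3)
      stop("box must be a T x 3 matrix")
  }
  structure(list(topology = topology, coords = coords,
                 times = times, box = box),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble:", n_frames(x), "frames x", n_atoms(x), "atoms")
  if (!is.null(x$times))
    cat(sprintf(" [%.3f, %.3f] ns", x$times[1], x$times[n_frames(x)]))
  cat("\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens an \code{ensemble}.
#' @return integer frame count.
#' @export
n_frames <- function(ens) dim(ens$coords)[3]

#' Extract one frame as an N x 3 coordinate matrix
#' @param ens an \code{ensemble}.
#' @param i frame index.
#' @return numeric \code{N x 3} matrix (nm).
#' @export
get_frame <- function(ens, i) {
  stopifnot(i >= 1L, i <= n_frames(ens))
  ens$coords[, , i, drop = TRUE]
}

#' Subset an ensemble by frame indices
#' @param ens an \code{ensemble}.
#' @param idx integer frame indices (in order).
#' @return \code{ensemble} with the selected frames.
#' @export
subset_frames <- function(ens, idx) {
  ensemble(ens$topology, ens$coords[, , idx, drop = FALSE],
           times = if (!is.null(ens$times)) ens$times[idx],
           box = if (!is.null(ens$box)) ens$box[idx, , drop = FALSE])
}

#' Discard the equilibration segment of a trajectory
#'
#' Removes all frames with timestamp earlier than \code{t_start}. Ensembles
#' without timestamps are trimmed by assuming frame index = time with unit
#' spacing starting at 0. An empty result is allowed but raised as a warning.
#'
#' @param ens an \code{ensemble}.
#' @param t_start equilibration time to discard (ns), >= 0. Typical
#'   production analyses discard an initial segment (e.g. 50 ns) during
#'   which the complex is still relaxing.
#' @return trimmed \code{ensemble}.
#' @export
trim_equilibration <- function(ens, t_start) {
  stopifnot(t_start >= 0)
  times <- if (!is.null(ens$times)) ens$times else seq_len(n_frames(ens)) - 1
  keep <- which(times >= t_start)
  if (!length(keep)) {
    warning("trim_equilibration: no frames at or after t_start = ", t_start,
            " ns; returning empty ensemble")
    out <- ens
    out$coords <- ens$coords[, , 0, drop = FALSE]
    if (!is.null(out$times)) out$times <- numeric(0)
    if (!is.null(out$box)) out$box <- ens$box[0, , drop = FALSE]
    return(out)
  }
  subset_frames(ens, keep)
}

# ---- selections --------------------------------------------------------

#' Resolve an atom selection on a topology
#'
#' Filters combine with AND; each filter may list several accepted values.
#' Resolution is deterministic and preserves topology atom order (except
#' \code{region}, which preserves the region's own declared order when it is
#' the only filter).
#'
#' @param top a \code{topology} (or \code{ensemble}, whose topology is used).
#' @param region region name in \code{top$region_map}.
#' @param chain chain id(s).
#' @param resno residue number(s) (e.g. \code{1:175}).
#' @param name atom name(s) (e.g. \code{"CA"}).
#' @param ids explicit atom ids to intersect with.
#' @return object of class \code{"selection"}: list with \code{ids}
#'   (integer atom ids) and \code{expr} (human-readable expression).
#' @export
select_atoms <- function(top, region = NULL, chain = NULL, resno = NULL,
                         name = NULL, ids = NULL) {
  if (inherits(top, "ensemble")) top <- top$topology
  atoms <- top$atoms
  expr <- character(0)
  keep_ids <- atoms$id
  if (!is.null(region)) {
    if (is.null(top$region_map[[region]]))
      stop("unknown region: ", region)
    keep_ids <- top$region_map[[region]]
    expr <- c(expr, paste0("region=", region))
  }
  filt <- rep(TRUE, nrow(atoms))
  if (!is.null(chain)) { filt <- filt & atoms$chain %in% chain
                         expr <- c(expr, paste0("chain=", paste(chain, collapse = "|"))) }
  if (!is.null(resno)) { filt <- filt & atoms$resno %in% resno
                         expr <- c(expr, paste0("resno=", paste(range(resno), collapse = "-"))) }
  if (!is.null(name))  { filt <- filt & atoms$name %in% name
                         expr <- c(expr, paste0("name=", paste(name, collapse = "|"))) }
  if (!is.null(ids))   { filt <- filt & atoms$id %in% ids
                         expr <- c(expr, "ids=<explicit>") }
  keep_ids <- keep_ids[keep_ids %in% atoms$id[filt]]
  structure(list(ids = as.integer(keep_ids),
                 expr = if (length(expr)) paste(expr, collapse = " & ") else "all"),
            class = "selection")
}

#' Union of two selections
#' @param a,b \code{selection} objects.
#' @return combined \code{selection} (order-preserving, duplicates removed).
#' @export
sel_union <- function(a, b) {
  structure(list(ids = unique(c(a$ids, b$ids)),
                 expr = paste0("(", a$expr, ") | (", b$expr, ")")),
            class = "selection")
}

#' Intersection of two selections
#' @param a,b \code{selection} objects.
#' @return combined \code{selection}.
#' @export
sel_intersect <- function(a, b) {
  structure(list(ids = a$ids[a$ids %in% b$ids],
                 expr = paste0("(", a$expr, ") & (", b$expr, ")")),
            class = "selection")
}

# Map a selection (or raw id vector, or NULL = all atoms) to row indices of
# the topology's atom table. Internal: all numeric kernels work on row indices.
sel_rows <- function(top, sel) {
  if (inherits(top, "ensemble")) top <- top$topology
  if (is.null(sel)) return(seq_len(nrow(top$atoms)))
  ids <- if (inherits(sel, "selection")) sel$ids else as.integer(sel)
  rows <- match(ids, top$atoms$id)
  if (anyNA(rows)) stop("selection references atom ids absent from topology")
  rows
}

#' Read a named-region definition file
#'
#' Regions are declared in YAML: each top-level key is a region name whose
#' value has a \code{chain} and a \code{resno} range given as
#' \code{[first, last]} (or a list of such ranges). The special key
#' \code{peptide} additionally receives position labels P1..Pn in residue
#' order.
#'
#' @param top a \code{topology}.
#' @param path path to the YAML region config.
#' @param name_filter restrict regions to atoms with these atom names
#'   (default \code{NULL} = all atoms of the matching residues).
#' @return the topology with \code{region_map} (and peptide labels) populated.
#' @export
read_region_config <- function(top, path, name_filter = NULL) {
  cfg <- yaml::read_yaml(path)
  rmap <- list()
  for (rn in names(cfg)) {
    spec <- cfg[[rn]]
    ranges <- spec$resno
    if (!is.list(ranges[[1]]) && !is.numeric(ranges[[1]])) ranges <- list(ranges)
    if (is.numeric(ranges) && length(ranges) == 2) ranges <- list(ranges)
    resnos <- unlist(lapply(ranges, function(r) seq(r[[1]], r[[2]])))
    sel <- select_atoms(top, chain = spec$chain, resno = resnos,
                        name = name_filter)
    if (!length(sel$ids))
      stop("region '", rn, "' resolves to zero atoms")
    rmap[[rn]] <- sel$ids
  }
  topology(top$atoms, rmap)
}
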