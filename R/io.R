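# Structure / trajectory readers and writers.
#
# Internally everything is in nm; PDB files (Angstrom) are converted on
# read/write. PDB parsing and DCD reading are delegated to bio3d; GRO is
# parsed here (fixed-width per the format definition).

.pdb_to_topology <- function(pdb) {
  at <- pdb$atom
  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(element == ""))
    element <- substr(trimws(at$elety), 1L, 1L)
  atoms <- data.frame(
    id = at$eleno, name = trimws(at$elety), element = trimws(element),
    resno = at$resno, resname = trimws(at$resid), chain = at$chain,
    insert = ifelse(is.na(at$insert), "", at$insert),
    stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  topology(atoms)
}

.read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("GRO parse error: file too short: ", path)
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms)) stop("GRO parse error at line 2: atom count expected")
  if (length(lines) < 2L + natoms + 1L)
    stop("GRO parse error: expected ", natoms, " atom lines")
  al <- lines[3:(2 + natoms)]
  resno <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resname <- trimws(substr(al, 6, 10))
  name <- trimws(substr(al, 11, 15))
  id <- suppressWarnings(as.integer(substr(al, 16, 20)))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("GRO parse error at line ", 2L + bad[1], " of ", path)
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[3L + natoms]),
                                              "\\s+")[[1]]))[1:3]
  atoms <- data.frame(id = id, name = name,
                      element = substr(name, 1L, 1L),
                      resno = resno, resname = resname, chain = "A",
                      insert = "", stringsAsFactors = FALSE)
  list(top = topology(atoms), xyz = cbind(x, y, z), box = box)
}

#' Read a structure file (PDB or GRO)
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or \code{"gro"}.
#' @return list with \code{topology} and a single-frame \code{ensemble}
#'   (coordinates in nm; GRO box vectors carried when present).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", gro = "gro",
                     stop("unsupported structure format: .", ext))
  }
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    top <- .pdb_to_topology(pdb)
    xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE) / 10  # A -> nm
    ens <- ensemble(top, xyz)
  } else {
    g <- .read_gro(path)
    top <- g$top
    ens <- ensemble(top, g$xyz, box = matrix(g$box, 1, 3))
  }
  list(topology = top, ensemble = ens)
}

#' Read a trajectory bound to an existing topology
#'
#' Supported formats: DCD and multi-model PDB. Timestamps are taken as
#' \code{t0 + (0:(T-1)) * dt} because neither format carries reliable
#' physical times.
#'
#' @param topology a \code{topology} the frames must match.
#' @param path trajectory file.
#' @param format \code{"auto"}, \code{"dcd"} or \code{"pdb"} (multi-model).
#' @param dt frame spacing in ns used to synthesize timestamps.
#' @param t0 time of the first frame (ns).
#' @return an \code{ensemble}.
#' @export
read_trajectory <- function(topology, path, format = c("auto", "dcd", "pdb"),
                            dt = 1, t0 = 0) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, dcd = "dcd", pdb = "pdb",
                     stop("unsupported trajectory format: .", ext))
  }
  if (format == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)   # T x 3N, Angstrom
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  }
  nat <- ncol(xyz) / 3L
  if (nat != nrow(topology$atoms))
    stop("topology mismatch: trajectory has ", nat, " atoms, topology has ",
         nrow(topology$atoms))
  nt <- nrow(xyz)
  coords <- array(0, c(nat, 3L, nt))
  for (t in seq_len(nt))
    coords[, , t] <- matrix(xyz[t, ], ncol = 3, byrow = TRUE) / 10
  ensemble(topology, coords, times = t0 + (seq_len(nt) - 1) * dt)
}

#' Write an ensemble as a (multi-model) PDB file
#'
#' @param ens an \code{ensemble} (one MODEL per frame).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_pdb_ensemble <- function(ens, path) {
  at <- ens$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  nt <- n_frames(ens)
  for (t in seq_len(nt)) {
    xyz <- get_frame(ens, t) * 10  # nm -> Angstrom
    writeLines(sprintf("MODEL     %4d", t), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$id %% 100000L, at$name, at$resname, substr(at$chain, 1, 1),
      at$resno %% 10000L, ifelse(is.na(at$insert), "", at$insert),
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, at$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a single frame as a GRO file
#'
#' @param ens an \code{ensemble}; frame \code{frame} is written.
#' @param path output path.
#' @param frame frame index (default 1).
#' @return invisibly, the path.
#' @export
write_gro <- function(ens, path, frame = 1L) {
  at <- ens$topology$atoms
  xyz <- get_frame(ens, frame)
  box <- if (!is.null(ens$box)) ens$box[frame, ] else c(0, 0, 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("written by tcrdyn", con)
  writeLines(sprintf("%5d", nrow(at)), con)
  writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     at$resno %% 100000L, at$resname, at$name,
                     at$id %% 100000L, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  invisible(path)
}
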