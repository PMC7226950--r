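# Hydrogen-bond detection, occupancy tables and peptide anchor analysis.
#
# Geometric criteria (configurable): donor-acceptor distance <= 0.35 nm
# and, when hydrogens exist in the topology, hydrogen-donor-acceptor angle
# <= 30 degrees. Topologies without hydrogens fall back to the distance
# criterion alone (flagged in the output).

.hbond_donors <- function(top, sel) {
  rows <- sel_rows(top, sel)
  at <- top$atoms
  heavy <- rows[at$element[rows] %in% c("N", "O")]
  # attached hydrogen: next atom in file order, same residue, element H
  hyd <- rep(NA_integer_, length(heavy))
  for (k in seq_along(heavy)) {
    r <- heavy[k]
    if (r < nrow(at) && at$element[r + 1L] == "H" &&
        at$resno[r + 1L] == at$resno[r] && at$chain[r + 1L] == at$chain[r])
      hyd[k] <- r + 1L
  }
  list(rows = heavy, hydrogen = hyd)
}

#' Detect hydrogen bonds in a single frame
#'
#' @param frame \code{N x 3} coordinates (nm).
#' @param top the \code{topology}.
#' @param donor_sel,acceptor_sel selections providing donor and acceptor
#'   heavy atoms (N/O); both required, non-empty.
#' @param d_cut donor-acceptor distance cutoff (nm), default 0.35.
#' @param angle_cut hydrogen-donor-acceptor angle cutoff (degrees), default
#'   30; ignored for donors without an attached hydrogen.
#' @return data.frame with one row per detected bond: donor/acceptor atom
#'   id, residue descriptors, distance (nm), angle (degrees, NA without
#'   hydrogen) and \code{criterion} ("distance+angle" or "distance-only").
#' @export
detect_hbonds <- function(frame, top, donor_sel, acceptor_sel,
                          d_cut = 0.35, angle_cut = 30) {
  don <- .hbond_donors(top, donor_sel)
  acc_rows <- sel_rows(top, acceptor_sel)
  acc_rows <- acc_rows[top$atoms$element[acc_rows] %in% c("N", "O")]
  if (!length(don$rows) || !length(acc_rows))
    stop("empty donor or acceptor selection (need N/O heavy atoms)")
  at <- top$atoms
  out <- list()
  for (k in seq_along(don$rows)) {
    d_row <- don$rows[k]
    dvec <- frame[acc_rows, , drop = FALSE] -
      matrix(frame[d_row, ], length(acc_rows), 3, byrow = TRUE)
    dist <- sqrt(rowSums(dvec^2))
    same <- acc_rows == d_row |
      (at$resno[acc_rows] == at$resno[d_row] &
         at$chain[acc_rows] == at$chain[d_row])
    cand <- which(dist <= d_cut & !same)
    if (!length(cand)) next
    ang <- rep(NA_real_, length(cand))
    keep <- rep(TRUE, length(cand))
    if (!is.na(don$hydrogen[k])) {
      hv <- frame[don$hydrogen[k], ] - frame[d_row, ]
      for (m in seq_along(cand)) {
        av <- dvec[cand[m], ]
        cosang <- sum(hv * av) / sqrt(sum(hv^2) * sum(av^2))
        ang[m] <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      }
      keep <- ang <= angle_cut
    }
    cand <- cand[keep]; ang <- ang[keep]
    if (!length(cand)) next
    a_rows <- acc_rows[cand]
    out[[length(out) + 1L]] <- data.frame(
      donor_id = at$id[d_row], acceptor_id = at$id[a_rows],
      donor_resname = at$resname[d_row], donor_resno = at$resno[d_row],
      donor_chain = at$chain[d_row],
      acceptor_resname = at$resname[a_rows], acceptor_resno = at$resno[a_rows],
      acceptor_chain = at$chain[a_rows],
      distance = dist[cand], angle = ang,
      criterion = ifelse(is.na(ang), "distance-only", "distance+angle"))
  }
  if (!length(out))
    return(data.frame(donor_id = integer(0), acceptor_id = integer(0),
                      donor_resname = character(0), donor_resno = integer(0),
                      donor_chain = character(0),
                      acceptor_resname = character(0),
                      acceptor_resno = integer(0),
                      acceptor_chain = character(0),
                      distance = numeric(0), angle = numeric(0),
                      criterion = character(0)))
  do.call(rbind, out)
}

# Map atom row -> peptide position label, NA outside the peptide region.
.pep_position <- function(top) {
  lab <- rep(NA_character_, nrow(top$atoms))
  pep <- top$region_map[["peptide"]]
  if (!is.null(pep))
    lab[match(pep, top$atoms$id)] <- top$pep_labels
  lab
}

#' Hydrogen-bond occupancy between the peptide and partner regions
#'
#' Detects bonds in every frame (peptide atoms may act as donors or
#' acceptors) and reports, for each (partner residue, peptide position)
#' pair ever seen, the fraction of frames in which at least one bond
#' between them satisfies the criteria.
#'
#' @param ens an \code{ensemble} whose topology has a labelled peptide
#'   region.
#' @param partner_selections named list of selections, e.g.
#'   \code{list(groove = ..., TCRa = ..., TCRb = ...)}.
#' @param d_cut,angle_cut geometric criteria (see
#'   \code{\link{detect_hbonds}}).
#' @return object of class \code{"occupancy_table"}: data.frame with
#'   \code{partner_group}, \code{partner_resname}, \code{partner_resno},
#'   \code{pep_pos} (label "P1"..), \code{occupancy} in [0, 1],
#'   \code{n_frames}.
#' @export
occupancy_table <- function(ens, partner_selections,
                            d_cut = 0.35, angle_cut = 30) {
  top <- ens$topology
  if (is.null(top$region_map[["peptide"]]))
    stop("topology has no labelled peptide region")
  pep_sel <- select_atoms(top, region = "peptide")
  pos <- .pep_position(top)
  nt <- n_frames(ens)
  counts <- new.env(parent = emptyenv())
  bump <- function(keys) for (key in unique(keys))
    assign(key, (if (exists(key, counts)) get(key, counts) else 0L) + 1L,
           counts)
  for (t in seq_len(nt)) {
    fr <- get_frame(ens, t)
    for (g in names(partner_selections)) {
      psel <- partner_selections[[g]]
      hb <- rbind(
        detect_hbonds(fr, top, donor_sel = psel, acceptor_sel = pep_sel,
                      d_cut = d_cut, angle_cut = angle_cut),
        detect_hbonds(fr, top, donor_sel = pep_sel, acceptor_sel = psel,
                      d_cut = d_cut, angle_cut = angle_cut))
      if (!nrow(hb)) next
      don_pos <- pos[match(hb$donor_id, top$atoms$id)]
      acc_pos <- pos[match(hb$acceptor_id, top$atoms$id)]
      pep_side_pos <- ifelse(is.na(acc_pos), don_pos, acc_pos)
      partner_resname <- ifelse(is.na(acc_pos), hb$acceptor_resname,
                                hb$donor_resname)
      partner_resno <- ifelse(is.na(acc_pos), hb$acceptor_resno,
                              hb$donor_resno)
      ok <- !is.na(pep_side_pos)
      if (!any(ok)) next
      bump(paste(g, partner_resname[ok], partner_resno[ok],
                 pep_side_pos[ok], sep = "\r"))
    }
  }
  keys <- ls(counts)
  if (!length(keys)) {
    out <- data.frame(partner_group = character(0),
                      partner_resname = character(0),
                      partner_resno = integer(0), pep_pos = character(0),
                      occupancy = numeric(0), n_frames = integer(0))
  } else {
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    out <- data.frame(partner_group = parts[, 1],
                      partner_resname = parts[, 2],
                      partner_resno = as.integer(parts[, 3]),
                      pep_pos = parts[, 4],
                      occupancy = vapply(keys, function(k) get(k, counts),
                                         1L) / nt,
                      n_frames = nt, row.names = NULL)
    out <- out[order(out$partner_group, out$partner_resno, out$pep_pos), ]
    rownames(out) <- NULL
  }
  class(out) <- c("occupancy_table", "data.frame")
  out
}

#' Presence matrix in the style of a bonds-per-position table
#'
#' Partner residues x peptide positions; a cell holds the peptide position
#' label when the pair's occupancy reaches \code{min_occupancy}.
#'
#' @param occ an \code{occupancy_table}.
#' @param min_occupancy presence threshold (default 0.1).
#' @return character matrix (rows "resname resno", columns "P1"...).
#' @export
presence_matrix <- function(occ, min_occupancy = 0.1) {
  keep <- occ[occ$occupancy >= min_occupancy, , drop = FALSE]
  if (!nrow(keep)) return(matrix(character(0), 0, 0))
  rows <- unique(paste(keep$partner_resname, keep$partner_resno))
  cols <- unique(keep$pep_pos[order(as.integer(sub("^P", "", keep$pep_pos)))])
  M <- matrix("", length(rows), length(cols), dimnames = list(rows, cols))
  for (i in seq_len(nrow(keep)))
    M[paste(keep$partner_resname[i], keep$partner_resno[i]),
      keep$pep_pos[i]] <- keep$pep_pos[i]
  M
}

#' Peptide anchor-site analysis
#'
#' Flags the two terminal anchor sites (persistent groove bonds at
#' positions P1-P2 and P(n-1)-Pn) and central TCR contacts (P4-P5), the
#' canonical class-I binding pattern.
#'
#' @param occ an \code{occupancy_table}.
#' @param min_occupancy occupancy needed to count a contact (default 0.1).
#' @param n_pep peptide length (default: largest position present).
#' @return object of class \code{"anchor_report"}: list with logical flags
#'   \code{n_terminal_anchor}, \code{c_terminal_anchor},
#'   \code{central_tcr_contacts}, the supporting rows per site, and the
#'   per-position groove contact counts.
#' @export
anchor_analysis <- function(occ, min_occupancy = 0.1, n_pep = NULL) {
  keep <- occ[occ$occupancy >= min_occupancy, , drop = FALSE]
  posnum <- as.integer(sub("^P", "", keep$pep_pos))
  if (is.null(n_pep))
    n_pep <- if (nrow(occ)) max(as.integer(sub("^P", "", occ$pep_pos))) else 0L
  groove <- keep$partner_group == "groove"
  tcr <- keep$partner_group %in% c("TCRa", "TCRb")
  nterm <- groove & posnum <= 2L
  cterm <- groove & n_pep > 0L & posnum >= n_pep - 1L
  central <- tcr & posnum %in% c(4L, 5L)
  per_pos <- if (nrow(keep[groove, ])) table(keep$pep_pos[groove]) else table(character(0))
  structure(list(
    n_terminal_anchor = any(nterm),
    c_terminal_anchor = any(cterm),
    central_tcr_contacts = any(central),
    n_terminal_rows = keep[nterm, , drop = FALSE],
    c_terminal_rows = keep[cterm, , drop = FALSE],
    central_rows = keep[central, , drop = FALSE],
    groove_contacts_per_position = per_pos,
    n_pep = n_pep, min_occupancy = min_occupancy),
    class = "anchor_report")
}

#' @export
print.anchor_report <- function(x, ...) {
  cat("anchor report (min occupancy", x$min_occupancy, "):\n")
  cat("  N-terminal anchor (P1-P2):  ", x$n_terminal_anchor, "\n")
  cat(sprintf("  C-terminal anchor (P%d-P%d):  %s\n",
              max(x$n_pep - 1L, 0L), x$n_pep, x$c_terminal_anchor))
  cat("  central TCR contacts (P4-P5):", x$central_tcr_contacts, "\n")
  invisible(x)
}
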