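# Nonbonded region-pair interaction energies.
#
# Descriptive cutoff energies between non-bonded regions:
#   Coulomb = sum f q_i q_j / (eps_r r_ij),  f = 138.935458 kJ mol^-1 nm e^-2
#   LJ      = sum 4 eps_ij [ (sig_ij/r)^12 - (sig_ij/r)^6 ]
# over cross pairs with r < cutoff (default 1.2 nm), Lorentz-Berthelot
# combination (sig_ij arithmetic mean, eps_ij geometric mean). Plain
# cutoff, no Ewald: these are per-pair descriptive statistics, not forces
# driving dynamics. No 1-4 exclusions: analysed regions are never
# covalently bonded to each other.

#' @rdname pair_energy
#' @format NULL
#' @export
COULOMB_CONSTANT <- 138.935458  # kJ mol^-1 nm e^-2

#' Coulomb and Lennard-Jones energy between two regions in one frame
#'
#' @param frame \code{N x 3} coordinates (nm).
#' @param top the \code{topology}; per-atom \code{charge}, \code{sigma},
#'   \code{epsilon} columns must cover both selections (see
#'   \code{\link{set_nonbonded_params}}).
#' @param sel_a,sel_b disjoint selections.
#' @param cutoff interaction cutoff (nm), default 1.2.
#' @param dielectric uniform relative dielectric for Coulomb (default 1).
#' @return list with \code{coulomb}, \code{lj} and \code{total} (kJ/mol).
#'   Pairs closer than 0.01 nm trigger a clash warning but are still
#'   evaluated.
#' @export
pair_energy <- function(frame, top, sel_a, sel_b, cutoff = 1.2,
                        dielectric = 1) {
  ra <- sel_rows(top, sel_a); rb <- sel_rows(top, sel_b)
  if (!length(ra) || !length(rb)) stop("empty selection")
  if (length(intersect(ra, rb))) stop("selections overlap")
  at <- top$atoms
  need <- c("charge", "sigma", "epsilon")
  if (any(vapply(need, function(cn) anyNA(at[[cn]][c(ra, rb)]), TRUE)))
    stop("missing nonbonded parameters; call set_nonbonded_params() or ",
         "read_param_table() first")
  A <- frame[ra, , drop = FALSE]; B <- frame[rb, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) - 2 * A %*% t(B) +
    outer(rep(1, nrow(A)), rowSums(B^2))
  r <- sqrt(pmax(d2, 0))
  within <- r < cutoff
  if (any(within & r < 0.01))
    warning("atomic clash: pair distance < 0.01 nm; energies reported anyway")
  r[r < 1e-6] <- 1e-6
  qq <- outer(at$charge[ra], at$charge[rb])
  coul <- sum((COULOMB_CONSTANT / dielectric) * qq[within] / r[within])
  sij <- outer(at$sigma[ra], at$sigma[rb], function(a, b) (a + b) / 2)
  eij <- sqrt(outer(at$epsilon[ra], at$epsilon[rb]))
  sr6 <- (sij[within] / r[within])^6
  lj <- sum(4 * eij[within] * (sr6^2 - sr6))
  list(coulomb = coul, lj = lj, total = coul + lj)
}

#' Interaction-energy series and distributions for region pairs
#'
#' Evaluates \code{\link{pair_energy}} on every frame for each requested
#' region pair (canonically peptide-groove, peptide-TCR, TCR-groove) and
#' returns per-frame series plus histogram summaries.
#'
#' @param ens an \code{ensemble} with nonbonded parameters on its topology.
#' @param region_pairs list of character pairs, e.g.
#'   \code{list(c("peptide", "groove"))}; names must exist in the
#'   topology's \code{region_map}.
#' @param cutoff interaction cutoff (nm).
#' @param dielectric uniform relative dielectric.
#' @param bins histogram bin count (default 30).
#' @return list with \code{series} (data.frame: pair, frame, coulomb, lj,
#'   total) and \code{summary} (data.frame: pair, mean, sd, mode of the
#'   total energy; mode = midpoint of the fullest histogram bin).
#' @export
energy_distribution <- function(ens, region_pairs, cutoff = 1.2,
                                dielectric = 1, bins = 30L) {
  top <- ens$topology
  nt <- n_frames(ens)
  rows <- list()
  for (rp in region_pairs) {
    sa <- select_atoms(top, region = rp[1])
    sb <- select_atoms(top, region = rp[2])
    lab <- paste(rp[1], rp[2], sep = "-")
    for (t in seq_len(nt)) {
      e <- pair_energy(get_frame(ens, t), top, sa, sb,
                       cutoff = cutoff, dielectric = dielectric)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = lab, frame = t, coulomb = e$coulomb, lj = e$lj,
        total = e$total)
    }
  }
  series <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(series, series$pair), function(s) {
    h <- graphics::hist(s$total, breaks = bins, plot = FALSE)
    data.frame(pair = s$pair[1], mean = mean(s$total),
               sd = stats::sd(s$total),
               mode = h$mids[which.max(h$counts)])
  }))
  rownames(summ) <- NULL
  list(series = series, summary = summ)
}

#' Read a whitespace-separated nonbonded parameter table
#'
#' Columns: \code{name} (atom name), \code{charge} (e), \code{sigma} (nm),
#' \code{epsilon} (kJ/mol). Parameters are matched to topology atoms by
#' atom name.
#'
#' @param top a \code{topology}.
#' @param path parameter file path.
#' @return topology with parameters attached.
#' @export
read_param_table <- function(top, path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("name", "charge", "sigma", "epsilon")
  if (!all(need %in% names(tab)))
    stop("parameter table needs columns: ", paste(need, collapse = ", "))
  set_nonbonded_params(top,
                       charge = stats::setNames(tab$charge, tab$name),
                       sigma = stats::setNames(tab$sigma, tab$name),
                       epsilon = stats::setNames(tab$epsilon, tab$name))
}
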