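# Synthetic pMHC-TCR fixtures with known ground truth.
#
# Every generator is a pure function of (spec, seed): same inputs, same
# output. Fluctuations are multivariate Gaussian because all the
# second-moment analyses downstream (essential dynamics, cross-correlation)
# are fully exercised by Gaussian statistics.

#' Displacement-mode specification for Gaussian ensemble sampling
#'
#' Describes a low-rank covariance Sigma = sum_k a_k v_k v_k' + eps * I over
#' the 3N Cartesian coordinates of a system.
#'
#' @param modes numeric \code{3N x K} matrix whose columns are mutually
#'   orthonormal displacement directions.
#' @param amplitudes numeric vector of K mode variances (nm^2), >= 0,
#'   sorted descending.
#' @param epsilon isotropic per-coordinate noise variance (nm^2), >= 0.
#' @return object of class \code{"mode_spec"}.
#' @export
mode_spec <- function(modes, amplitudes, epsilon = 0) {
  modes <- as.matrix(modes)
  if (length(amplitudes) != ncol(modes))
    stop("one amplitude per mode required")
  if (any(amplitudes < 0) || epsilon < 0)
    stop("amplitudes and epsilon must be >= 0")
  if (is.unsorted(rev(amplitudes)))
    stop("amplitudes must be sorted descending")
  gram <- crossprod(modes)
  if (max(abs(gram - diag(ncol(modes)))) > 1e-8)
    stop("mode directions must be mutually orthonormal")
  structure(list(modes = modes, amplitudes = amplitudes, epsilon = epsilon),
            class = "mode_spec")
}

# Region layout used by the toy complex: compact Gaussian clouds on
# well-separated centres so that regions are spatially segregated.
.toy_region_centres <- list(
  groove  = c(0, 0, 0),
  peptide = c(0, 0, 1.2),
  Valpha  = c(-1.5, 0, 2.8),
  Vbeta   = c(1.5, 0, 2.8),
  Calpha  = c(-1.5, 0, 5.2),
  Cbeta   = c(1.5, 0, 5.2))

.toy_chains <- c(groove = "A", peptide = "C", Valpha = "D", Vbeta = "E",
                 Calpha = "D", Cbeta = "E")

#' Build a toy pMHC-TCR complex at C-alpha resolution
#'
#' One pseudo-atom per residue; the six canonical regions (binding groove,
#' peptide, TCR variable domains Valpha/Vbeta, TCR constant domains
#' Calpha/Cbeta) are laid out as spatially segregated clouds. Peptide
#' residues take their names from \code{peptide_sequence} and are labelled
#' P1..Pn in sequence order.
#'
#' @param region_sizes named integer vector with at least entries
#'   \code{groove}, \code{Valpha}, \code{Vbeta}, \code{Calpha}, \code{Cbeta}
#'   (the peptide size comes from the sequence). Default emulates a class-I
#'   groove of 175 residues with compact 15-residue TCR domains.
#' @param peptide_sequence one-letter peptide sequence (default the 9-mer
#'   NY-ESO-1 tumor epitope SLLMWITQC).
#' @param seed integer RNG seed.
#' @param spread cloud standard deviation per region (nm).
#' @return list with \code{topology} and single-frame \code{ensemble}
#'   (the reference structure).
#' @export
make_toy_complex <- function(region_sizes = c(groove = 175, Valpha = 15,
                                              Vbeta = 15, Calpha = 15,
                                              Cbeta = 15),
                             peptide_sequence = "SLLMWITQC",
                             seed = 1L, spread = 0.5) {
  need <- c("groove", "Valpha", "Vbeta", "Calpha", "Cbeta")
  if (!all(need %in% names(region_sizes)))
    stop("region_sizes must name: ", paste(need, collapse = ", "))
  pep <- strsplit(peptide_sequence, "")[[1]]
  sizes <- c(groove = unname(region_sizes["groove"]),
             peptide = length(pep),
             Valpha = unname(region_sizes["Valpha"]),
             Vbeta = unname(region_sizes["Vbeta"]),
             Calpha = unname(region_sizes["Calpha"]),
             Cbeta = unname(region_sizes["Cbeta"]))
  set.seed(seed)
  rows <- list(); xyz <- list(); rmap <- list(); next_id <- 1L
  for (rn in names(sizes)) {
    n <- sizes[[rn]]
    ids <- seq.int(next_id, length.out = n)
    next_id <- next_id + n
    resname <- if (rn == "peptide") bio3d::aa123(pep) else
      sample(c("ALA", "GLY", "SER", "LEU", "VAL", "THR"), n, replace = TRUE)
    rows[[rn]] <- data.frame(
      id = ids, name = "CA", element = "C",
      resno = seq_len(n), resname = resname,
      chain = .toy_chains[[rn]], insert = "", stringsAsFactors = FALSE)
    ctr <- .toy_region_centres[[rn]]
    xyz[[rn]] <- cbind(stats::rnorm(n, ctr[1], spread),
                       stats::rnorm(n, ctr[2], spread),
                       stats::rnorm(n, ctr[3], spread))
    rmap[[rn]] <- ids
  }
  atoms <- do.call(rbind, rows)
  # constant domains share the variable domains' chains; renumber to follow on
  atoms$resno[atoms$chain == "D" & seq_len(nrow(atoms)) %in% rmap$Calpha] <-
    seq_along(rmap$Calpha) + sizes[["Valpha"]]
  atoms$resno[atoms$chain == "E" & seq_len(nrow(atoms)) %in% rmap$Cbeta] <-
    seq_along(rmap$Cbeta) + sizes[["Vbeta"]]
  top <- topology(atoms, rmap)
  ref <- do.call(rbind, xyz)
  list(topology = top, ensemble = ensemble(top, ref))
}

#' Sample a Gaussian ensemble with prescribed covariance
#'
#' Frames are \code{ref + sum_k sqrt(a_k) z_tk v_k + sqrt(eps) eta_t} with
#' iid standard normal \code{z}, \code{eta}, so the population covariance of
#' the coordinates is exactly \code{Sigma = V diag(a) V' + eps I}. Frames are
#' generated pre-aligned (no global drift is added), so covariance-based
#' analyses recover the planted spectrum without superposition.
#'
#' @param top a \code{topology}.
#' @param reference reference frame, \code{N x 3} matrix (nm).
#' @param spec a \code{\link{mode_spec}}.
#' @param n_frames number of frames (>= 2).
#' @param seed integer RNG seed.
#' @return an \code{ensemble} with unit-spaced timestamps.
#' @export
sample_ensemble <- function(top, reference, spec, n_frames, seed = 1L) {
  stopifnot(inherits(spec, "mode_spec"), n_frames >= 2)
  nat <- nrow(top$atoms)
  if (nrow(spec$modes) != 3L * nat)
    stop("mode length must be 3N = ", 3L * nat)
  set.seed(seed)
  K <- ncol(spec$modes)
  z <- matrix(stats::rnorm(n_frames * K), n_frames, K)
  disp <- z %*% (t(spec$modes) * sqrt(spec$amplitudes))  # T x 3N
  if (spec$epsilon > 0)
    disp <- disp + matrix(stats::rnorm(n_frames * 3L * nat,
                                       sd = sqrt(spec$epsilon)),
                          n_frames, 3L * nat)
  coords <- array(0, c(nat, 3L, n_frames))
  refv <- as.vector(t(reference))                 # x1 y1 z1 x2 ...
  for (t in seq_len(n_frames))
    coords[, , t] <- matrix(refv + disp[t, ], ncol = 3, byrow = TRUE)
  ensemble(top, coords, times = seq_len(n_frames) - 1)
}

#' Orthonormal displacement mode moving two regions along one axis
#'
#' Utility for planting correlated / anticorrelated region pairs: all atoms
#' of region A move along \code{axis} with weight +1 and all atoms of region
#' B with weight \code{sign_b}; the mode is normalised to unit length.
#'
#' @param top a \code{topology}.
#' @param sel_a,sel_b selections (see \code{\link{select_atoms}}).
#' @param axis length-3 direction (default x).
#' @param sign_b +1 (in-phase) or -1 (antiphase).
#' @return numeric vector of length 3N, unit norm.
#' @export
region_pair_mode <- function(top, sel_a, sel_b, axis = c(1, 0, 0),
                             sign_b = -1) {
  axis <- axis / sqrt(sum(axis^2))
  v <- numeric(3L * nrow(top$atoms))
  for (r in sel_rows(top, sel_a)) v[(3 * r - 2):(3 * r)] <- axis
  for (r in sel_rows(top, sel_b)) v[(3 * r - 2):(3 * r)] <- sign_b * axis
  v / sqrt(sum(v^2))
}

#' Sample an ensemble with a planted inter-region correlation
#'
#' Atoms of region A are displaced rigidly along \code{axis} by a standard
#' normal amplitude \code{z1}; atoms of region B by
#' \code{rho * z1 + sqrt(1-rho^2) * z2}. The displacement correlation
#' between any A-atom and any B-atom is therefore exactly \code{rho};
#' remaining atoms receive isotropic jitter.
#'
#' @param top a \code{topology}.
#' @param sel_a,sel_b disjoint selections.
#' @param rho target correlation in [-1, 1].
#' @param n_frames number of frames.
#' @param sigma displacement scale (nm).
#' @param jitter isotropic noise sd (nm) for atoms outside A and B.
#' @param seed RNG seed.
#' @param reference \code{N x 3} reference frame; default all zeros layout
#'   from the topology is not available, so a reference must be given.
#' @return an \code{ensemble}.
#' @export
sample_correlated_pair <- function(top, reference, sel_a, sel_b, rho,
                                   n_frames, sigma = 0.1, jitter = 0.02,
                                   axis = c(1, 0, 0), seed = 1L) {
  stopifnot(abs(rho) <= 1)
  ra <- sel_rows(top, sel_a); rb <- sel_rows(top, sel_b)
  if (length(intersect(ra, rb))) stop("selections must be disjoint")
  set.seed(seed)
  nat <- nrow(top$atoms)
  axis <- axis / sqrt(sum(axis^2))
  z1 <- stats::rnorm(n_frames); z2 <- stats::rnorm(n_frames)
  zb <- rho * z1 + sqrt(1 - rho^2) * z2
  other <- setdiff(seq_len(nat), c(ra, rb))
  coords <- array(0, c(nat, 3L, n_frames))
  for (t in seq_len(n_frames)) {
    fr <- reference
    fr[ra, ] <- fr[ra, , drop = FALSE] +
      matrix(sigma * z1[t] * axis, length(ra), 3, byrow = TRUE)
    fr[rb, ] <- fr[rb, , drop = FALSE] +
      matrix(sigma * zb[t] * axis, length(rb), 3, byrow = TRUE)
    if (length(other) && jitter > 0)
      fr[other, ] <- fr[other, , drop = FALSE] +
        matrix(stats::rnorm(3 * length(other), sd = jitter), length(other), 3)
    coords[, , t] <- fr
  }
  ensemble(top, coords, times = seq_len(n_frames) - 1)
}

#' Bilayer geometry specification
#'
#' @param lx,ly lateral extent (nm).
#' @param d mean leaflet separation / thickness (nm), > 0.
#' @param amplitude undulation amplitude (nm).
#' @param wavelength undulation wavelength (nm).
#' @param antiphase if TRUE the two leaflets undulate in antiphase
#'   (thickness varies in [d - 2a, d + 2a]); if FALSE in phase (thickness
#'   constant).
#' @param sigma per-headgroup z noise sd (nm), >= 0.
#' @param n_lipids headgroups per leaflet.
#' @param drift_per_frame change of d per frame (nm); planted thinning when
#'   negative.
#' @return object of class \code{"bilayer_spec"}.
#' @export
bilayer_spec <- function(lx = 10, ly = 10, d = 4, amplitude = 0,
                         wavelength = 5, antiphase = TRUE, sigma = 0,
                         n_lipids = 400, drift_per_frame = 0) {
  stopifnot(d > 0, sigma >= 0, n_lipids >= 2)
  structure(list(lx = lx, ly = ly, d = d, amplitude = amplitude,
                 wavelength = wavelength, antiphase = antiphase,
                 sigma = sigma, n_lipids = n_lipids,
                 drift_per_frame = drift_per_frame),
            class = "bilayer_spec")
}

# Deterministic leaflet surfaces; exported so tests can check per-cell
# thickness against the analytic ground truth.
#' Analytic leaflet surfaces of a synthetic bilayer
#' @param spec a \code{\link{bilayer_spec}}.
#' @param x,y lateral coordinates (nm).
#' @param frame frame index (drift applies from frame 1).
#' @return list with \code{upper} and \code{lower} z (nm).
#' @export
bilayer_surfaces <- function(spec, x, y, frame = 1L) {
  d_t <- spec$d + spec$drift_per_frame * (frame - 1L)
  und <- spec$amplitude * sin(2 * pi * x / spec$wavelength)
  upper <- d_t / 2 + und
  lower <- -d_t / 2 + if (spec$antiphase) -und else und
  list(upper = upper, lower = lower)
}

#' Generate a two-leaflet headgroup point set
#'
#' Headgroup pseudo-atoms ("P") are laid out uniformly at random in the
#' lateral plane (same xy for every frame) with z on the analytic leaflet
#' surfaces plus iid Gaussian noise redrawn each frame. Leaflets are
#' labelled by chain: "U" upper, "L" lower.
#'
#' @param spec a \code{\link{bilayer_spec}}.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return list with \code{topology}, \code{ensemble} (box = lateral extent)
#'   and \code{truth} (the spec).
#' @export
make_bilayer <- function(spec, n_frames = 1L, seed = 1L) {
  stopifnot(inherits(spec, "bilayer_spec"))
  set.seed(seed)
  n <- spec$n_lipids
  xu <- stats::runif(n, 0, spec$lx); yu <- stats::runif(n, 0, spec$ly)
  xl <- stats::runif(n, 0, spec$lx); yl <- stats::runif(n, 0, spec$ly)
  atoms <- data.frame(
    id = seq_len(2L * n), name = "P", element = "P",
    resno = c(seq_len(n), seq_len(n)),
    resname = "POPC",
    chain = rep(c("U", "L"), each = n), insert = "",
    stringsAsFactors = FALSE)
  top <- topology(atoms, list(upper = seq_len(n), lower = n + seq_len(n)))
  coords <- array(0, c(2L * n, 3L, n_frames))
  for (t in seq_len(n_frames)) {
    su <- bilayer_surfaces(spec, xu, yu, t)
    sl <- bilayer_surfaces(spec, xl, yl, t)
    zu <- su$upper; zl <- sl$lower
    if (spec$sigma > 0) {
      zu <- zu + stats::rnorm(n, sd = spec$sigma)
      zl <- zl + stats::rnorm(n, sd = spec$sigma)
    }
    coords[, , t] <- rbind(cbind(xu, yu, zu), cbind(xl, yl, zl))
  }
  ens <- ensemble(top, coords, times = seq_len(n_frames) - 1,
                  box = matrix(rep(c(spec$lx, spec$ly, 4 * spec$d),
                                   n_frames), n_frames, 3, byrow = TRUE))
  list(topology = top, ensemble = ens, truth = spec)
}

#' Generate donor-acceptor geometries with prescribed H-bond occupancies
#'
#' Each requested pair gets a donor nitrogen (with an attached hydrogen) in
#' a partner residue and an acceptor oxygen in a peptide residue. In a
#' fraction of frames equal (in expectation) to the pair's target occupancy
#' the acceptor sits at 0.29 nm from the donor with the hydrogen collinear
#' (satisfying a 0.35 nm / 30 degree criterion); otherwise at 0.55 nm
#' (violating it). Pairs are spaced >= 3 nm apart so no spurious cross-pair
#' bonds arise.
#'
#' @param pairs data.frame with columns \code{partner_resname},
#'   \code{partner_resno}, \code{partner_group} (one of "groove", "TCRa",
#'   "TCRb") and \code{pep_pos} (integer peptide position).
#' @param occupancy_targets numeric vector in [0, 1], one per pair.
#' @param n_frames number of frames.
#' @param n_pep peptide length (default 9).
#' @param seed RNG seed.
#' @return list with \code{topology}, \code{ensemble} and \code{truth}
#'   (pairs + target and realized occupancies).
#' @export
make_hbond_trajectory <- function(pairs, occupancy_targets, n_frames,
                                  n_pep = 9L, seed = 1L) {
  stopifnot(nrow(pairs) == length(occupancy_targets),
            all(occupancy_targets >= 0 & occupancy_targets <= 1),
            all(pairs$pep_pos >= 1 & pairs$pep_pos <= n_pep))
  set.seed(seed)
  npair <- nrow(pairs)
  group_chain <- c(groove = "A", TCRa = "D", TCRb = "E")
  # peptide backbone: one CA per position, chain C
  pep_atoms <- data.frame(
    id = seq_len(n_pep), name = "CA", element = "C", resno = seq_len(n_pep),
    resname = "ALA", chain = "C", insert = "", stringsAsFactors = FALSE)
  rows <- list(pep_atoms); next_id <- n_pep + 1L
  base <- matrix(0, npair, 3)
  u <- matrix(0, npair, 3)
  for (i in seq_len(npair)) {
    base[i, ] <- c(3 * i, 0, 0)
    th <- stats::runif(1, 0, 2 * pi); ph <- acos(stats::runif(1, -1, 1))
    u[i, ] <- c(sin(ph) * cos(th), sin(ph) * sin(th), cos(ph))
    ch <- group_chain[[pairs$partner_group[i]]]
    rows[[i + 1L]] <- data.frame(
      id = next_id + 0:2,
      name = c("N", "H", "O"), element = c("N", "H", "O"),
      resno = c(pairs$partner_resno[i], pairs$partner_resno[i],
                pairs$pep_pos[i]),
      resname = c(pairs$partner_resname[i], pairs$partner_resname[i], "ALA"),
      chain = c(ch, ch, "C"), insert = "", stringsAsFactors = FALSE)
    next_id <- next_id + 3L
  }
  atoms <- do.call(rbind, rows)
  donor_ids <- n_pep + 3L * (seq_len(npair) - 1L) + 1L
  acceptor_ids <- donor_ids + 2L
  rmap <- list(peptide = c(seq_len(n_pep), acceptor_ids[order(pairs$pep_pos)]))
  # peptide region holds CA plus acceptor atoms; labels must follow residue order
  pep_ids <- c(seq_len(n_pep), acceptor_ids)
  pep_resno <- atoms$resno[match(pep_ids, atoms$id)]
  ord <- order(pep_resno, pep_ids)
  rmap$peptide <- pep_ids[ord]
  for (g in unique(pairs$partner_group))
    rmap[[g]] <- sort(c(donor_ids[pairs$partner_group == g],
                        donor_ids[pairs$partner_group == g] + 1L))
  top <- topology(atoms, rmap,
                  pep_labels = paste0("P", pep_resno[ord]))
  bonded <- matrix(stats::runif(n_frames * npair), n_frames, npair) <
    matrix(occupancy_targets, n_frames, npair, byrow = TRUE)
  nat <- nrow(atoms)
  coords <- array(0, c(nat, 3L, n_frames))
  pep_xyz <- cbind(seq_len(n_pep) * 0.4, -3, 0)   # static peptide backbone
  for (t in seq_len(n_frames)) {
    fr <- matrix(0, nat, 3)
    fr[seq_len(n_pep), ] <- pep_xyz
    for (i in seq_len(npair)) {
      dist_da <- if (bonded[t, i]) 0.29 else 0.55
      d_row <- match(donor_ids[i], atoms$id)
      fr[d_row, ] <- base[i, ]                       # donor N
      fr[d_row + 1L, ] <- base[i, ] + 0.10 * u[i, ]  # H, collinear
      fr[d_row + 2L, ] <- base[i, ] + dist_da * u[i, ]
    }
    coords[, , t] <- fr
  }
  truth <- cbind(pairs,
                 target_occupancy = occupancy_targets,
                 realized_occupancy = colMeans(bonded))
  list(topology = top,
       ensemble = ensemble(top, coords, times = seq_len(n_frames) - 1),
       truth = truth)
}

#' Attach toy nonbonded parameters (charges, LJ) to a topology
#'
#' Assigns per-atom charge and Lennard-Jones parameters either from a named
#' lookup by atom name or from explicit vectors. Used by the energy module
#' fixtures; not a force field.
#'
#' @param top a \code{topology}.
#' @param charge numeric vector (recycled) or named lookup by atom name (e).
#' @param sigma LJ sigma (nm), same conventions.
#' @param epsilon LJ well depth (kJ/mol).
#' @return the topology with parameter columns filled.
#' @export
set_nonbonded_params <- function(top, charge = 0, sigma = 0.3,
                                 epsilon = 0.5) {
  at <- top$atoms
  fill <- function(x, default) {
    if (!is.null(names(x))) {
      v <- unname(x[at$name]); v[is.na(v)] <- default; v
    } else rep_len(x, nrow(at))
  }
  at$charge <- fill(charge, 0)
  at$sigma <- fill(sigma, 0.3)
  at$epsilon <- fill(epsilon, 0)
  if (any(at$sigma <= 0)) stop("sigma must be > 0")
  if (any(at$epsilon < 0)) stop("epsilon must be >= 0")
  topology(at, top$region_map, top$pep_labels)
}
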