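# Superposition and fluctuation measures.
#
# RMSD(t)  = sqrt( (1/N) sum_i |r_i(t) - r_i^0|^2 )
# RMSF(i)  = sqrt( (1/T) sum_t |r_i(t) - ref_i|^2 )
# with ref the first frame (default, matching the usual trajectory
# convention) or the time average.

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation R (det = +1) and translation that minimise the
#' squared deviation of \code{mobile} from \code{reference} over the fit
#' selection, and applies it to the whole mobile frame.
#'
#' @param mobile,reference \code{N x 3} coordinate matrices (nm).
#' @param sel fit selection (a \code{selection}, atom-id vector, or NULL =
#'   all atoms); must contain >= 3 non-collinear atoms.
#' @param top topology used to resolve \code{sel}; required when \code{sel}
#'   is a selection object.
#' @return list with \code{coords} (transformed mobile frame),
#'   \code{rotation} (3x3), \code{translation} (length 3, applied after
#'   rotation about the fit centroid) and \code{rmsd} (post-fit RMSD over
#'   the fit selection, nm).
#' @export
superpose <- function(mobile, reference, sel = NULL, top = NULL) {
  rows <- if (is.null(sel)) seq_len(nrow(mobile)) else sel_rows(top, sel)
  if (length(rows) < 3L) stop("degenerate selection: need >= 3 atoms to fit")
  A <- mobile[rows, , drop = FALSE]
  B <- reference[rows, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  # collinearity check: rank of the centred fit coordinates
  if (qr(Ac)$rank < 2L || qr(Bc)$rank < 2L)
    stop("degenerate selection: fit atoms are collinear")
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  out <- sweep(mobile, 2, ca) %*% t(R)
  out <- sweep(out, 2, cb, `+`)
  fitted <- out[rows, , drop = FALSE]
  list(coords = out, rotation = R, translation = cb - ca,
       rmsd = sqrt(mean(rowSums((fitted - B)^2))))
}

#' Superpose every frame of an ensemble onto a reference frame
#'
#' @param ens an \code{ensemble}.
#' @param reference \code{N x 3} reference coordinates.
#' @param sel fit selection (NULL = all atoms).
#' @return the ensemble with every frame least-squares fitted.
#' @export
superpose_ensemble <- function(ens, reference, sel = NULL) {
  out <- ens
  for (t in seq_len(n_frames(ens)))
    out$coords[, , t] <- superpose(get_frame(ens, t), reference,
                                   sel = sel, top = ens$topology)$coords
  out
}

#' Per-frame RMSD from a reference structure
#'
#' @param ens an \code{ensemble}.
#' @param reference reference frame (\code{N x 3}); default the first frame
#'   of the ensemble.
#' @param sel measurement selection (NULL = all atoms).
#' @param fit if TRUE (default) each frame is least-squares superposed onto
#'   the reference over \code{fit_sel} before measuring.
#' @param fit_sel fit selection; defaults to the measurement selection.
#' @return object of class \code{"rmsd_series"}: data.frame with columns
#'   \code{frame}, \code{time} (ns, when available) and \code{rmsd} (nm);
#'   attributes record selection and fit convention.
#' @export
rmsd_series <- function(ens, reference = NULL, sel = NULL, fit = TRUE,
                        fit_sel = NULL) {
  rows <- sel_rows(ens, sel)
  if (!length(rows)) stop("empty selection")
  if (is.null(reference)) reference <- get_frame(ens, 1L)
  if (is.null(fit_sel)) fit_sel <- sel
  nt <- n_frames(ens)
  vals <- numeric(nt)
  refsel <- reference[rows, , drop = FALSE]
  for (t in seq_len(nt)) {
    fr <- get_frame(ens, t)
    if (fit)
      fr <- superpose(fr, reference, sel = fit_sel, top = ens$topology)$coords
    vals[t] <- sqrt(mean(rowSums((fr[rows, , drop = FALSE] - refsel)^2)))
  }
  out <- data.frame(frame = seq_len(nt),
                    time = if (!is.null(ens$times)) ens$times else NA_real_,
                    rmsd = vals)
  attr(out, "fitted") <- fit
  attr(out, "selection") <- if (inherits(sel, "selection")) sel$expr else "all"
  class(out) <- c("rmsd_series", "data.frame")
  out
}

#' Per-atom (and per-residue) RMSF
#'
#' Root mean square fluctuation of each selected atom about a reference
#' position: the initial structure (\code{reference_mode = "initial"}, the
#' default) or the time-averaged structure (\code{"mean"}). The mean-mode
#' value is the per-atom positional standard deviation and is always <=
#' the initial-mode value.
#'
#' @param ens an \code{ensemble} with >= 2 frames.
#' @param sel measurement selection (NULL = all atoms).
#' @param reference_mode \code{"initial"} or \code{"mean"}.
#' @param fit if TRUE (default) frames are superposed onto the reference
#'   structure over \code{fit_sel} first.
#' @param fit_sel fit selection; defaults to the measurement selection.
#' @return object of class \code{"rmsf_profile"}: data.frame with columns
#'   \code{id}, \code{resno}, \code{chain}, \code{rmsf} (nm).
#' @export
rmsf_profile <- function(ens, sel = NULL,
                         reference_mode = c("initial", "mean"),
                         fit = TRUE, fit_sel = NULL) {
  reference_mode <- match.arg(reference_mode)
  if (n_frames(ens) < 2L) stop("RMSF needs >= 2 frames")
  rows <- sel_rows(ens, sel)
  if (!length(rows)) stop("empty selection")
  if (is.null(fit_sel)) fit_sel <- sel
  work <- ens
  ref0 <- get_frame(ens, 1L)
  if (fit) work <- superpose_ensemble(ens, ref0, sel = fit_sel)
  X <- work$coords[rows, , , drop = FALSE]           # n x 3 x T
  refmat <- if (reference_mode == "initial") {
    (if (fit) get_frame(work, 1L) else ref0)[rows, , drop = FALSE]
  } else {
    apply(X, c(1, 2), mean)
  }
  dev2 <- sweep(X, c(1, 2), refmat)^2
  vals <- sqrt(apply(dev2, 1, sum) / dim(X)[3])
  at <- ens$topology$atoms[rows, ]
  out <- data.frame(id = at$id, resno = at$resno, chain = at$chain,
                    rmsf = vals)
  attr(out, "reference_mode") <- reference_mode
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' Aggregate an atom-level RMSF profile to residue level
#'
#' Residue value = mean of its atoms' RMSF (profiles are usually plotted
#' per residue).
#'
#' @param profile an \code{rmsf_profile}.
#' @return data.frame with \code{chain}, \code{resno}, \code{rmsf}.
#' @export
rmsf_by_residue <- function(profile) {
  agg <- stats::aggregate(rmsf ~ chain + resno, data = profile, FUN = mean)
  agg[order(agg$chain, agg$resno), , drop = FALSE]
}
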