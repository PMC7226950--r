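# Dynamic cross-correlation map (DCCM) with threshold classification.
#
# C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>), dr the per-atom
# deviation from its mean position (after the same superposition
# convention as the covariance module, so C and Sigma stay consistent).
# Classification bands follow the study convention: correlated when the
# value exceeds 0.75 (strictly), anticorrelated on the closed band
# [-1, -0.25], neutral otherwise.

#' Dynamic cross-correlation matrix
#'
#' @param ens an \code{ensemble} with >= 2 frames.
#' @param sel atom selection (NULL = all atoms).
#' @param fit superpose frames onto the ensemble mean first (default TRUE);
#'   use FALSE for pre-aligned ensembles.
#' @return object of class \code{"correlation_matrix"}: symmetric
#'   \code{n x n} matrix in [-1, 1] with unit diagonal; attributes
#'   \code{ids}, \code{rows}. Atoms with zero positional variance get
#'   correlation 0 against everything (and 1 on the diagonal), with a
#'   warning.
#' @export
cross_correlation_matrix <- function(ens, sel = NULL, fit = TRUE) {
  if (n_frames(ens) < 2L) stop("cross-correlation needs >= 2 frames")
  rows <- sel_rows(ens, sel)
  if (!length(rows)) stop("empty selection")
  X <- .coord_matrix(ens, rows)                     # T x 3n
  if (fit && length(rows) >= 3L) {
    target <- .row_to_mat(X[1, ])
    for (pass in 1:2) {
      Xf <- .fit_rows(X, target)
      target <- .row_to_mat(colMeans(Xf))
    }
    X <- .fit_rows(X, target)
  }
  D <- sweep(X, 2, colMeans(X))
  n <- length(rows)
  Dx <- D[, seq(1, 3 * n, 3), drop = FALSE]
  Dy <- D[, seq(2, 3 * n, 3), drop = FALSE]
  Dz <- D[, seq(3, 3 * n, 3), drop = FALSE]
  S <- (crossprod(Dx) + crossprod(Dy) + crossprod(Dz)) / nrow(D)
  v <- diag(S)
  zero <- v <= 0
  if (any(zero))
    warning(sum(zero), " atom(s) with zero variance; correlations set to 0")
  denom <- sqrt(v)
  denom[zero] <- 1
  C <- S / outer(denom, denom)
  C[zero, ] <- 0; C[, zero] <- 0
  diag(C) <- 1
  C <- pmin(pmax(C, -1), 1)
  attr(C, "ids") <- ens$topology$atoms$id[rows]
  attr(C, "rows") <- rows
  class(C) <- c("correlation_matrix", class(C))
  C
}

#' Classify a correlation matrix into correlated / anticorrelated / neutral
#'
#' Bands: value > 0.75 -> "correlated"; -1 <= value <= -0.25 ->
#' "anticorrelated"; anything in (-0.25, 0.75] -> "neutral". Boundary
#' handling is literal: 0.75 itself is neutral, -0.25 itself is
#' anticorrelated.
#'
#' @param C a \code{correlation_matrix} (or plain numeric matrix in
#'   [-1, 1]).
#' @param tol numerical tolerance for the [-1, 1] validity check.
#' @return character matrix of the same shape with entries
#'   \code{"correlated"}, \code{"anticorrelated"}, \code{"neutral"}.
#' @export
classify_correlations <- function(C, tol = 1e-9) {
  M <- unclass(C)
  if (any(M > 1 + tol | M < -1 - tol))
    stop("correlation values outside [-1, 1]")
  out <- matrix("neutral", nrow(M), ncol(M))
  out[M > 0.75] <- "correlated"
  out[M <= -0.25] <- "anticorrelated"
  dimnames(out) <- dimnames(M)
  out
}

#' Region-pair summary of a correlation matrix
#'
#' For every unordered pair of (disjoint) regions, reports the mean
#' off-block correlation and the fractions of entries in the correlated
#' and anticorrelated bands.
#'
#' @param C a \code{correlation_matrix} whose atoms carry ids (attribute
#'   \code{ids}).
#' @param top the \code{topology} providing \code{region_map}.
#' @param regions region names to summarise (default: all mapped regions).
#' @return data.frame with \code{region_a}, \code{region_b},
#'   \code{mean_corr}, \code{frac_correlated}, \code{frac_anticorrelated},
#'   \code{n_pairs}.
#' @export
region_block_summary <- function(C, top, regions = names(top$region_map)) {
  ids <- attr(C, "ids")
  if (is.null(ids)) stop("matrix lacks atom ids; use cross_correlation_matrix")
  idx <- lapply(regions, function(r) {
    m <- match(intersect(top$region_map[[r]], ids), ids)
    m[!is.na(m)]
  })
  names(idx) <- regions
  for (i in seq_along(idx)) for (j in seq_along(idx)) {
    if (i < j && length(intersect(idx[[i]], idx[[j]])))
      stop("regions overlap: ", regions[i], " and ", regions[j])
  }
  cls <- classify_correlations(C)
  rows <- list()
  for (i in seq_along(regions)) for (j in i:length(regions)) {
    bi <- idx[[i]]; bj <- idx[[j]]
    if (!length(bi) || !length(bj)) next
    block <- unclass(C)[bi, bj, drop = FALSE]
    bcls <- cls[bi, bj, drop = FALSE]
    if (i == j) {  # exclude the diagonal from within-region stats
      keep <- !diag(TRUE, length(bi))
      vals <- block[keep]; lab <- bcls[keep]
    } else {
      vals <- as.vector(block); lab <- as.vector(bcls)
    }
    if (!length(vals)) next
    rows[[length(rows) + 1L]] <- data.frame(
      region_a = regions[i], region_b = regions[j],
      mean_corr = mean(vals),
      frac_correlated = mean(lab == "correlated"),
      frac_anticorrelated = mean(lab == "anticorrelated"),
      n_pairs = length(vals))
  }
  do.call(rbind, rows)
}
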