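# Essential dynamics: positional covariance analysis of selected atoms
# (usually C-alpha), eigen-decomposition into collective modes, 2D
# projections, and common subspaces built from concatenated trajectories of
# systems with matched atom counts.
#
# Conventions (fixed here because upstream workflows leave them implicit):
#  - frames are least-squares fitted onto the ensemble mean before the
#    covariance is accumulated, with two mean-refinement passes;
#  - covariance uses the 1/T (population) normalisation, so the variance of
#    the projection of the generating ensemble along eigenvector k equals
#    the eigenvalue lambda_k exactly.

# T x 3n coordinate matrix (row t = x1 y1 z1 x2 ...) for selected rows.
.coord_matrix <- function(ens, rows) {
  nt <- n_frames(ens)
  X <- matrix(0, nt, 3L * length(rows))
  for (t in seq_len(nt))
    X[t, ] <- as.vector(t(ens$coords[rows, , t]))
  X
}

.row_to_mat <- function(v) matrix(v, ncol = 3, byrow = TRUE)

# Fit every row of X (T x 3n) onto target (n x 3), fitting over all atoms.
.fit_rows <- function(X, target) {
  out <- X
  for (t in seq_len(nrow(X)))
    out[t, ] <- as.vector(t(superpose(.row_to_mat(X[t, ]), target)$coords))
  out
}

#' Positional covariance matrix of an ensemble
#'
#' Entry (3i+a, 3j+b) is the covariance of coordinate a of atom i with
#' coordinate b of atom j across frames, after optional superposition onto
#' the (iteratively refined) ensemble mean.
#'
#' @param ens an \code{ensemble} with >= 2 frames.
#' @param sel atom selection (NULL = all atoms).
#' @param fit superpose frames onto the ensemble mean first (default TRUE).
#'   Use FALSE for pre-aligned ensembles, e.g. synthetic ones.
#' @return \code{3n x 3n} symmetric PSD matrix (nm^2) with attributes
#'   \code{mean} (n x 3 deviation origin), \code{fit_target} (n x 3 fit
#'   reference, when fitted), \code{rows}, \code{ids}, \code{fitted},
#'   \code{n_frames}.
#' @export
covariance_matrix <- function(ens, sel = NULL, fit = TRUE) {
  if (n_frames(ens) < 2L) stop("covariance needs >= 2 frames")
  rows <- sel_rows(ens, sel)
  if (!length(rows)) stop("empty selection")
  X <- .coord_matrix(ens, rows)
  fit_target <- NULL
  if (fit && length(rows) >= 3L) {
    target <- .row_to_mat(X[1, ])
    for (pass in 1:2) {
      Xf <- .fit_rows(X, target)
      target <- .row_to_mat(colMeans(Xf))
    }
    Xf <- .fit_rows(X, target)
    fit_target <- target
  } else {
    Xf <- X
    fit <- FALSE
  }
  mu <- colMeans(Xf)
  D <- sweep(Xf, 2, mu)
  C <- crossprod(D) / nrow(D)
  attr(C, "mean") <- .row_to_mat(mu)
  attr(C, "fit_target") <- fit_target
  attr(C, "rows") <- rows
  attr(C, "ids") <- ens$topology$atoms$id[rows]
  attr(C, "fitted") <- fit
  attr(C, "n_frames") <- nrow(D)
  C
}

#' Diagonalize a positional covariance matrix
#'
#' @param C symmetric covariance matrix, typically from
#'   \code{\link{covariance_matrix}} (whose metadata is carried over).
#' @param tol asymmetry tolerance.
#' @param systems character vector naming the source system(s).
#' @return object of class \code{"essential_subspace"}: list with
#'   \code{vectors} (3n x 3n orthonormal columns), \code{values} (nm^2,
#'   descending, clamped at 0), \code{mean}, \code{fit_target},
#'   \code{ids}, \code{fitted}, \code{systems}, \code{trace}.
#' @export
diagonalize <- function(C, tol = 1e-8, systems = "system") {
  if (!isSymmetric(unclass(C), tol = tol * max(1, max(abs(C)))))
    stop("covariance matrix must be symmetric")
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- e$values
  if (any(vals < -tol * max(abs(vals), 1)))
    warning("covariance has eigenvalues below -tol; clamping to 0")
  vals <- pmax(vals, 0)
  structure(list(vectors = e$vectors, values = vals,
                 mean = attr(C, "mean"), fit_target = attr(C, "fit_target"),
                 ids = attr(C, "ids"), fitted = isTRUE(attr(C, "fitted")),
                 systems = systems, trace = sum(diag(C))),
            class = "essential_subspace")
}

#' @export
print.essential_subspace <- function(x, ...) {
  cat("essential subspace:", length(x$values), "modes;",
      "lambda1 =", signif(x$values[1], 4), "nm^2;",
      "var(k=2) =", signif(variance_fraction(x, 2), 4), "\n")
  invisible(x)
}

#' One-call essential dynamics of an ensemble
#' @inheritParams covariance_matrix
#' @param system system label stored in the result.
#' @return an \code{essential_subspace}.
#' @export
essential_dynamics <- function(ens, sel = NULL, fit = TRUE,
                               system = "system") {
  diagonalize(covariance_matrix(ens, sel = sel, fit = fit), systems = system)
}

#' Fraction of total variance captured by the first k modes
#'
#' @param subspace an \code{essential_subspace}.
#' @param k number of leading eigenvectors.
#' @return scalar in [0, 1]; 0 (with a warning) for a zero spectrum.
#' @export
variance_fraction <- function(subspace, k) {
  stopifnot(k >= 1, k <= length(subspace$values))
  tot <- sum(subspace$values)
  if (tot == 0) {
    warning("zero total variance; returning 0")
    return(0)
  }
  sum(subspace$values[seq_len(k)]) / tot
}

#' Project an ensemble onto the leading eigenvectors of a subspace
#'
#' Each frame is (optionally) superposed onto the subspace's fit reference
#' and its deviation from the subspace mean projected onto eigenvectors
#' 1..k.
#'
#' @param ens an \code{ensemble}.
#' @param subspace an \code{essential_subspace}.
#' @param k number of components (default 2).
#' @param sel selection resolving to the same atom count as the subspace;
#'   default: the subspace's own atom ids.
#' @param system label attached to the projection.
#' @return object of class \code{"projection2d"}: data.frame with
#'   \code{frame}, \code{system} and columns \code{pc1..pck} (nm).
#' @export
project_ensemble <- function(ens, subspace, k = 2, sel = NULL,
                             system = "system") {
  rows <- if (is.null(sel)) {
    r <- match(subspace$ids, ens$topology$atoms$id)
    if (anyNA(r)) stop("subspace atom ids not present; supply sel explicitly")
    r
  } else sel_rows(ens, sel)
  if (3L * length(rows) != nrow(subspace$vectors))
    stop("selection atom count (", length(rows),
         ") does not match subspace (", nrow(subspace$vectors) / 3L, ")")
  X <- .coord_matrix(ens, rows)
  if (subspace$fitted) X <- .fit_rows(X, subspace$fit_target)
  D <- sweep(X, 2, as.vector(t(subspace$mean)))
  P <- D %*% subspace$vectors[, seq_len(k), drop = FALSE]
  out <- data.frame(frame = seq_len(nrow(P)), system = system)
  for (j in seq_len(k)) out[[paste0("pc", j)]] <- P[, j]
  attr(out, "subspace_id") <- .subspace_id(subspace)
  class(out) <- c("projection2d", "data.frame")
  out
}

.subspace_id <- function(s)
  paste0("ss-", nrow(s$vectors), "-", signif(sum(s$values), 12))

#' Common essential subspace of several systems
#'
#' Concatenates the (equal-atom-count) selected coordinates of all systems,
#' jointly superposes them, builds one covariance, and projects every
#' system into the common plane. Every frame carries equal weight
#' regardless of which system it comes from.
#'
#' @param ensembles named list of \code{ensemble}s.
#' @param selections list of selections, one per system (NULL entries =
#'   all atoms); all must resolve to the same atom count. Atom
#'   correspondence is positional (region-relative order).
#' @param fit superpose onto the joint mean (default TRUE).
#' @param k number of projection components.
#' @return list with \code{subspace} (an \code{essential_subspace}) and
#'   \code{projections} (one \code{projection2d} per system).
#' @export
combined_subspace <- function(ensembles, selections = NULL, fit = TRUE,
                              k = 2) {
  if (is.null(names(ensembles)))
    names(ensembles) <- paste0("system", seq_along(ensembles))
  if (is.null(selections)) selections <- vector("list", length(ensembles))
  rows_list <- mapply(function(e, s) sel_rows(e, s), ensembles, selections,
                      SIMPLIFY = FALSE)
  counts <- lengths(rows_list)
  if (length(unique(counts)) != 1L)
    stop("unequal atom counts across systems: ",
         paste(sprintf("%s=%d", names(ensembles), counts), collapse = ", "))
  Xs <- mapply(function(e, r) .coord_matrix(e, r), ensembles, rows_list,
               SIMPLIFY = FALSE)
  X <- do.call(rbind, Xs)
  fit_target <- NULL
  if (fit && counts[1] >= 3L) {
    target <- .row_to_mat(X[1, ])
    for (pass in 1:2) {
      Xf <- .fit_rows(X, target)
      target <- .row_to_mat(colMeans(Xf))
    }
    Xf <- .fit_rows(X, target)
    fit_target <- target
  } else {
    Xf <- X
    fit <- FALSE
  }
  mu <- colMeans(Xf)
  D <- sweep(Xf, 2, mu)
  C <- crossprod(D) / nrow(D)
  attr(C, "mean") <- .row_to_mat(mu)
  attr(C, "fit_target") <- fit_target
  attr(C, "fitted") <- fit
  ss <- diagonalize(C, systems = names(ensembles))
  ss$ids <- NULL  # atom ids differ across systems; projections go via sel
  offsets <- c(0, cumsum(vapply(Xs, nrow, 1L)))
  projections <- list()
  for (i in seq_along(ensembles)) {
    Pi <- Xs[[i]]
    if (fit) Pi <- .fit_rows(Pi, fit_target)
    Dv <- sweep(Pi, 2, mu)
    P <- Dv %*% ss$vectors[, seq_len(k), drop = FALSE]
    pr <- data.frame(frame = seq_len(nrow(P)), system = names(ensembles)[i])
    for (j in seq_len(k)) pr[[paste0("pc", j)]] <- P[, j]
    attr(pr, "subspace_id") <- .subspace_id(ss)
    class(pr) <- c("projection2d", "data.frame")
    projections[[names(ensembles)[i]]] <- pr
  }
  list(subspace = ss, projections = projections)
}

#' Overlap score of two projection clouds in a common subspace
#'
#' The joint bounding box of both clouds is divided into an
#' \code{n_grid x n_grid} raster; the score is the Jaccard overlap of the
#' sets of occupied cells: 1 for identical support, 0 for disjoint clouds.
#'
#' @param proj_a,proj_b \code{projection2d} objects from the same common
#'   subspace.
#' @param n_grid raster resolution per axis (default 50).
#' @return scalar in [0, 1].
#' @export
subspace_overlap <- function(proj_a, proj_b, n_grid = 50L) {
  ia <- attr(proj_a, "subspace_id"); ib <- attr(proj_b, "subspace_id")
  if (!is.null(ia) && !is.null(ib) && !identical(ia, ib))
    stop("projections come from different subspaces")
  xs <- range(c(proj_a$pc1, proj_b$pc1))
  ys <- range(c(proj_a$pc2, proj_b$pc2))
  if (diff(xs) == 0) xs <- xs + c(-0.5, 0.5)
  if (diff(ys) == 0) ys <- ys + c(-0.5, 0.5)
  cell <- function(p) {
    cx <- pmin(pmax(ceiling((p$pc1 - xs[1]) / diff(xs) * n_grid), 1L), n_grid)
    cy <- pmin(pmax(ceiling((p$pc2 - ys[1]) / diff(ys) * n_grid), 1L), n_grid)
    unique(cx + n_grid * (cy - 1L))
  }
  ca <- cell(proj_a); cb <- cell(proj_b)
  length(intersect(ca, cb)) / length(union(ca, cb))
}

#' Principal angles between two sets of planted/recovered mode directions
#'
#' Used to verify parameter recovery: the largest principal angle between
#' span(A) and span(B), in degrees.
#'
#' @param A,B matrices with orthonormal columns (same row dimension).
#' @return largest principal angle (degrees).
#' @export
subspace_angle <- function(A, B) {
  sv <- svd(crossprod(A, B))$d
  sv <- pmin(pmax(sv, -1), 1)
  max(acos(sv)) * 180 / pi
}
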