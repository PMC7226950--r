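# Grid-based bilayer thickness and inter-selection minimum distance.
#
# Thickness follows the GridMAT-style recipe: the lateral plane is divided
# into an n_x x n_y grid (default 100 x 100) and each cell's thickness is
# the z of the nearest upper-leaflet headgroup to the cell centre minus
# the z of the nearest lower-leaflet headgroup. Distances are
# minimum-image aware when a box is present.

#' Partition headgroups into upper and lower leaflets
#'
#' Split by the sign of z relative to the midplane (mean headgroup z).
#'
#' @param frame \code{N x 3} coordinates (nm).
#' @param top the \code{topology}.
#' @param headgroup_sel selection of headgroup atoms (NULL = all).
#' @return list with integer atom-id vectors \code{upper} and \code{lower}.
#' @export
assign_leaflets <- function(frame, top, headgroup_sel = NULL) {
  rows <- sel_rows(top, headgroup_sel)
  if (length(rows) < 2L) stop("need >= 2 headgroups")
  z <- frame[rows, 3]
  mid <- mean(z)
  up <- rows[z > mid]; lo <- rows[z < mid]
  if (!length(up) || !length(lo))
    stop("degenerate bilayer: all headgroups on one side of the midplane")
  list(upper = top$atoms$id[up], lower = top$atoms$id[lo])
}

# lateral minimum-image displacement
.lat_mi <- function(dx, L) if (is.null(L) || !is.finite(L) || L <= 0) dx else
  dx - L * round(dx / L)

#' Bilayer thickness on a lateral grid
#'
#' @param frame \code{N x 3} coordinates (nm).
#' @param top the \code{topology}.
#' @param leaflets list with \code{upper}/\code{lower} atom ids (from
#'   \code{\link{assign_leaflets}}).
#' @param n_x,n_y grid resolution (default 100 x 100).
#' @param box optional lateral box lengths \code{c(lx, ly)} (nm); the grid
#'   then spans \code{[0, lx] x [0, ly]} with periodic lateral distances,
#'   otherwise the headgroups' bounding box.
#' @return object of class \code{"thickness_map"}: list with \code{values}
#'   (\code{n_x x n_y} matrix, nm), \code{x}, \code{y} cell centres,
#'   \code{occupied} (logical matrix; with nearest-neighbour assignment
#'   every cell is occupied when both leaflets are non-empty).
#' @export
thickness_map <- function(frame, top, leaflets, n_x = 100L, n_y = 100L,
                          box = NULL) {
  up <- frame[sel_rows(top, leaflets$upper), , drop = FALSE]
  lo <- frame[sel_rows(top, leaflets$lower), , drop = FALSE]
  if (!nrow(up) || !nrow(lo)) stop("empty leaflet")
  if (is.null(box)) {
    xr <- range(c(up[, 1], lo[, 1])); yr <- range(c(up[, 2], lo[, 2]))
    lx <- ly <- NULL
  } else {
    xr <- c(0, box[1]); yr <- c(0, box[2]); lx <- box[1]; ly <- box[2]
  }
  cx <- xr[1] + (seq_len(n_x) - 0.5) * diff(xr) / n_x
  cy <- yr[1] + (seq_len(n_y) - 0.5) * diff(yr) / n_y
  nearest_z <- function(pts) {
    zz <- matrix(0, n_x, n_y)
    for (j in seq_len(n_y)) {
      dy <- .lat_mi(pts[, 2] - cy[j], ly)
      for (i in seq_len(n_x)) {
        dx <- .lat_mi(pts[, 1] - cx[i], lx)
        zz[i, j] <- pts[which.min(dx * dx + dy * dy), 3]
      }
    }
    zz
  }
  vals <- nearest_z(up) - nearest_z(lo)
  structure(list(values = vals, x = cx, y = cy,
                 occupied = matrix(TRUE, n_x, n_y)),
            class = "thickness_map")
}

#' Compare mean thickness between trajectory halves
#'
#' Computes the thickness-map mean for every frame, splits the trajectory
#' into first and second half, and reports per-half mean/sd plus the
#' difference (second minus first). A stationary bilayer gives a
#' difference within sampling noise of zero; planted thinning shows up
#' directly.
#'
#' @param ens an \code{ensemble} of a bilayer system.
#' @param headgroup_sel headgroup selection.
#' @param n_x,n_y grid resolution.
#' @return data.frame with one row: \code{mean_first}, \code{sd_first},
#'   \code{mean_second}, \code{sd_second}, \code{difference},
#'   \code{low_confidence} (TRUE when a half has < 2 frames).
#' @export
thickness_comparison <- function(ens, headgroup_sel = NULL,
                                 n_x = 100L, n_y = 100L) {
  nt <- n_frames(ens)
  if (nt < 2L) stop("need >= 2 frames to compare halves")
  means <- numeric(nt)
  for (t in seq_len(nt)) {
    fr <- get_frame(ens, t)
    lf <- assign_leaflets(fr, ens$topology, headgroup_sel)
    box <- if (!is.null(ens$box)) ens$box[t, 1:2]
    means[t] <- mean(thickness_map(fr, ens$topology, lf,
                                   n_x = n_x, n_y = n_y, box = box)$values)
  }
  h <- nt %/% 2L
  first <- means[seq_len(h)]; second <- means[(h + 1L):nt]
  data.frame(mean_first = mean(first), sd_first = stats::sd(first),
             mean_second = mean(second), sd_second = stats::sd(second),
             difference = mean(second) - mean(first),
             low_confidence = (length(first) < 2L || length(second) < 2L))
}

#' Minimum inter-selection distance per frame
#'
#' Per-frame minimum over all cross pairs of Euclidean distance between
#' two selections, minimum-image aware when the ensemble carries a box.
#'
#' @param ens an \code{ensemble}.
#' @param sel_a,sel_b non-empty selections.
#' @return data.frame with \code{frame}, \code{time}, \code{distance}
#'   (nm).
#' @export
bilayer_distance_series <- function(ens, sel_a, sel_b) {
  ra <- sel_rows(ens, sel_a); rb <- sel_rows(ens, sel_b)
  if (!length(ra) || !length(rb)) stop("empty selection")
  nt <- n_frames(ens)
  out <- numeric(nt)
  for (t in seq_len(nt)) {
    fr <- get_frame(ens, t)
    A <- fr[ra, , drop = FALSE]; B <- fr[rb, , drop = FALSE]
    box <- if (!is.null(ens$box)) ens$box[t, ]
    d2 <- matrix(0, nrow(A), nrow(B))
    for (k in 1:3) {
      dk <- outer(A[, k], B[, k], `-`)
      if (!is.null(box) && is.finite(box[k]) && box[k] > 0)
        dk <- dk - box[k] * round(dk / box[k])
      d2 <- d2 + dk * dk
    }
    out[t] <- sqrt(min(d2))
  }
  data.frame(frame = seq_len(nt),
             time = if (!is.null(ens$times)) ens$times else NA_real_,
             distance = out)
}
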