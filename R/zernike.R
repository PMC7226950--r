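# 3D Zernike descriptors of region shape and electrostatics.
#
# A region is voxelized onto a cubic grid normalised into the unit ball
# (content scaled to radius 0.7 to avoid boundary truncation). Moments
# Omega_nl^m = (3/4pi) * Int f(x) conj(Z_nl^m(x)) dx are computed by
# expanding each basis function Z_nl^m = R_nl(r) Y_l^m into Cartesian
# monomials and contracting against the grid's geometric moments; the
# rotation-invariant descriptor is F_nl = sqrt(sum_m |Omega_nl^m|^2).
#
# Basis conventions: orthonormal complex spherical harmonics built from
# Racah-normalised regular solid harmonics via the recursions
#   R_00 = 1
#   R_ll = -sqrt((2l-1)/(2l)) (x+iy) R_{l-1,l-1}
#   R_lm = [(2l-1) z R_{l-1,m} - sqrt((l-1)^2-m^2) r^2 R_{l-2,m}]
#          / sqrt(l^2-m^2)
# and radial polynomials R_nl(r) = sum_nu q_klnu r^(2nu+l), k = (n-l)/2,
# with the standard coefficients making the basis orthonormal under
# (3/4pi) Int over the unit ball.

.default_radii <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152,
                    S = 0.180, P = 0.180)

#' Construct a voxel grid object
#'
#' @param values numeric \code{M x M x M} array of non-negative voxel
#'   values; the grid is taken to span \code{[-1, 1]^3} (unit-ball
#'   normalised coordinates).
#' @param channel one of \code{"shape"}, \code{"electrostatics+"},
#'   \code{"electrostatics-"}.
#' @param origin,spacing physical provenance (nm), optional.
#' @return object of class \code{"voxel_grid"}.
#' @export
voxel_grid <- function(values, channel = "shape", origin = NULL,
                       spacing = NULL) {
  d <- dim(values)
  if (length(d) != 3L || length(unique(d)) != 1L)
    stop("values must be a cubic M x M x M array")
  if (any(!is.finite(values)) || any(values < 0))
    stop("voxel values must be finite and >= 0")
  structure(list(values = values, M = d[1], channel = channel,
                 origin = origin, spacing = spacing),
            class = "voxel_grid")
}

# Voxel centre coordinates along one axis for an M-grid on [-1, 1].
.voxel_axis <- function(M) -1 + (seq_len(M) - 0.5) * 2 / M

#' Voxelize the union-of-spheres shape of a selection
#'
#' Atoms become spheres of (element-default or supplied) radius inflated by
#' a probe radius; voxels inside any sphere get value 1. The selection is
#' centred on its centroid and isotropically scaled so the outermost sphere
#' surface sits at radius \code{ball_fill} (default 0.7) of the unit ball.
#'
#' @param frame \code{N x 3} coordinates (nm).
#' @param top the \code{topology}.
#' @param sel atom selection (NULL = all).
#' @param radii named per-element radii (nm); defaults cover H/C/N/O/S/P,
#'   others 0.17.
#' @param M grid side in voxels (default 64).
#' @param probe probe inflation radius (nm, default 0.14).
#' @param ball_fill fraction of the unit ball the content is scaled to.
#' @return a \code{voxel_grid} (channel "shape") with attributes
#'   \code{scale} (nm -> unit-ball factor) and \code{centroid} (nm).
#' @export
voxelize_shape <- function(frame, top, sel = NULL, radii = NULL,
                           M = 64L, probe = 0.14, ball_fill = 0.7) {
  rows <- sel_rows(top, sel)
  if (!length(rows)) stop("empty selection")
  rt <- .default_radii
  if (!is.null(radii)) rt[names(radii)] <- radii
  el <- top$atoms$element[rows]
  r_at <- unname(rt[el]); r_at[is.na(r_at)] <- 0.17
  r_at <- r_at + probe
  xyz <- frame[rows, , drop = FALSE]
  centroid <- colMeans(xyz)
  xyz <- sweep(xyz, 2, centroid)
  extent <- max(sqrt(rowSums(xyz^2)) + r_at)
  scale <- ball_fill / extent
  xyz <- xyz * scale
  r_at <- r_at * scale
  ax <- .voxel_axis(M)
  vals <- array(0, c(M, M, M))
  h <- 2 / M
  for (a in seq_along(r_at)) {
    ctr <- xyz[a, ]; ra <- r_at[a]
    ix <- which(ax >= ctr[1] - ra - h & ax <= ctr[1] + ra + h)
    iy <- which(ax >= ctr[2] - ra - h & ax <= ctr[2] + ra + h)
    iz <- which(ax >= ctr[3] - ra - h & ax <= ctr[3] + ra + h)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (ax[ix] - ctr[1])^2
    dy2 <- (ax[iy] - ctr[2])^2
    dz2 <- (ax[iz] - ctr[3])^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= ra^2
    vals[ix, iy, iz][inside] <- 1
  }
  if (sum(vals) == 0)
    stop("voxelization produced an empty grid (selection of ",
         length(rows), " atoms, M = ", M, ")")
  g <- voxel_grid(vals, channel = "shape")
  attr(g, "scale") <- scale
  attr(g, "centroid") <- centroid
  g
}

# Surface voxels: occupied with at least one empty 6-neighbour.
.surface_mask <- function(vals) {
  M <- dim(vals)[1]
  occ <- vals > 0
  full <- array(TRUE, dim(vals))
  shift_and <- function(acc, dim, by) {
    nb <- array(FALSE, c(M, M, M))
    idx_src <- list(1:M, 1:M, 1:M); idx_dst <- idx_src
    idx_dst[[dim]] <- (1:M) + by
    keep <- idx_dst[[dim]] >= 1 & idx_dst[[dim]] <= M
    idx_dst[[dim]] <- idx_dst[[dim]][keep]
    idx_src[[dim]] <- (1:M)[keep]
    nb[idx_src[[1]], idx_src[[2]], idx_src[[3]]] <-
      occ[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]]
    acc & nb
  }
  for (d in 1:3) for (b in c(-1L, 1L)) full <- shift_and(full, d, b)
  occ & !full
}

#' Voxelize the electrostatic potential of a selection
#'
#' The shape grid's surface voxels are assigned a potential value, split
#' into a positive channel max(phi, 0) and a negative channel max(-phi, 0).
#' Potentials come either from an external per-point table (nearest point
#' wins) or from an internal Coulomb sum over the selection's per-atom
#' charges with a uniform dielectric.
#'
#' @param frame,top,sel,radii,M,probe,ball_fill as in
#'   \code{\link{voxelize_shape}}.
#' @param potential optional data.frame \code{x, y, z, phi} (nm, any
#'   potential unit) of externally computed potentials.
#' @param dielectric uniform relative dielectric for the Coulomb fallback.
#' @return list with \code{positive} and \code{negative}
#'   \code{voxel_grid}s.
#' @export
voxelize_electrostatics <- function(frame, top, sel = NULL, potential = NULL,
                                    radii = NULL, M = 64L, probe = 0.14,
                                    ball_fill = 0.7, dielectric = 1) {
  rows <- sel_rows(top, sel)
  charges <- top$atoms$charge[rows]
  if (is.null(potential) && all(is.na(charges)))
    stop("no charge source: supply per-atom charges in the topology or an ",
         "external potential table (x y z phi)")
  shape <- voxelize_shape(frame, top, sel, radii = radii, M = M,
                          probe = probe, ball_fill = ball_fill)
  surf <- .surface_mask(shape$values)
  idx <- which(surf, arr.ind = TRUE)
  ax <- .voxel_axis(M)
  # voxel centres back in physical nm coordinates
  scale <- attr(shape, "scale"); centroid <- attr(shape, "centroid")
  pts <- cbind(ax[idx[, 1]], ax[idx[, 2]], ax[idx[, 3]]) / scale
  pts <- sweep(pts, 2, centroid, `+`)
  if (!is.null(potential)) {
    pm <- as.matrix(potential[, c("x", "y", "z")])
    phi <- potential$phi[max.col(-(
      outer(rowSums(pts^2), rep(1, nrow(pm))) -
        2 * pts %*% t(pm) +
        outer(rep(1, nrow(pts)), rowSums(pm^2))))]
  } else {
    q <- charges; q[is.na(q)] <- 0
    xyz <- frame[rows, , drop = FALSE]
    ke <- 138.935458 / dielectric   # kJ mol^-1 nm e^-2
    phi <- numeric(nrow(pts))
    for (a in seq_len(nrow(xyz))) {
      dr <- sqrt(rowSums(sweep(pts, 2, xyz[a, ])^2))
      dr[dr < 1e-6] <- 1e-6
      phi <- phi + ke * q[a] / dr
    }
  }
  pos <- array(0, dim(shape$values)); neg <- pos
  pos[surf] <- pmax(phi, 0)
  neg[surf] <- pmax(-phi, 0)
  list(positive = voxel_grid(pos, channel = "electrostatics+"),
       negative = voxel_grid(neg, channel = "electrostatics-"))
}

# ---- Zernike basis coefficient machinery -------------------------------

# Radial coefficients q_{k nu}^l of R_nl(r) = sum_nu q r^(2nu+l), k=(n-l)/2.
.zernike_q <- function(k, l) {
  nu <- 0:k
  lchoose2 <- function(a, b) lgamma(a + 1) - lgamma(b + 1) - lgamma(a - b + 1)
  sgn <- (-1)^k * (-1)^nu
  logmag <- -2 * k * log(2) + 0.5 * (log(2 * l + 4 * k + 3) - log(3)) +
    lchoose2(2 * k, k) + lchoose2(k, nu) +
    lchoose2(2 * (k + l + nu) + 1, 2 * k) - lchoose2(k + l + nu, k)
  sgn * exp(logmag)
}

# Monomial coefficient arrays of the Racah solid harmonics R_lm, m >= 0,
# up to degree lmax. Returns list [[l+1]][[m+1]] of complex arrays with
# dims (lmax+1)^3 indexed [p+1, q+1, r+1] for x^p y^q z^r.
.solid_harmonics <- function(lmax) {
  d <- lmax + 1L
  zero <- array(complex(real = 0), c(d, d, d))
  shift <- function(P, dim) {
    out <- zero
    if (dim == 1) out[2:d, , ] <- P[1:(d - 1), , ]
    if (dim == 2) out[, 2:d, ] <- P[, 1:(d - 1), ]
    if (dim == 3) out[, , 2:d] <- P[, , 1:(d - 1)]
    out
  }
  mul_r2 <- function(P) shift(shift(P, 1), 1) + shift(shift(P, 2), 2) +
    shift(shift(P, 3), 3)
  S <- vector("list", lmax + 1L)
  S[[1]] <- list(zero)
  S[[1]][[1]][1, 1, 1] <- 1 + 0i
  if (lmax >= 1) {
    for (l in 1:lmax) {
      S[[l + 1]] <- vector("list", l + 1L)
      # diagonal m = l
      prev <- S[[l]][[l]]
      S[[l + 1]][[l + 1]] <- -sqrt((2 * l - 1) / (2 * l)) *
        (shift(prev, 1) + 1i * shift(prev, 2))
      for (m in 0:(l - 1)) {
        t1 <- (2 * l - 1) * shift(S[[l]][[m + 1]], 3)
        t2 <- if (l >= 2 && m <= l - 2)
          sqrt((l - 1)^2 - m^2) * mul_r2(S[[l - 1]][[m + 1]]) else zero
        S[[l + 1]][[m + 1]] <- (t1 - t2) / sqrt(l^2 - m^2)
      }
    }
  }
  S
}

# Cached monomial expansion of every Z_nl^m (m >= 0) up to order N:
# for each entry, integer monomial indices into a flattened (N+1)^3 array
# and complex coefficients.
.zernike_env <- new.env(parent = emptyenv())

.zernike_table <- function(N) {
  key <- paste0("N", N)
  if (!is.null(.zernike_env[[key]])) return(.zernike_env[[key]])
  d <- N + 1L
  S <- .solid_harmonics(N)
  # promote solid-harmonic arrays (dims (N+1)^3 already) to Y_lm scale
  yscale <- function(l) sqrt(2 * l + 1)
  zero <- array(complex(real = 0), c(d, d, d))
  shiftz2 <- function(P) {  # multiply by r^2 = x^2 + y^2 + z^2
    sx <- zero; sx[3:d, , ] <- P[1:(d - 2), , ]
    sy <- zero; sy[, 3:d, ] <- P[, 1:(d - 2), ]
    sz <- zero; sz[, , 3:d] <- P[, , 1:(d - 2)]
    sx + sy + sz
  }
  entries <- list()
  for (n in 0:N) for (l in seq(n %% 2, n, by = 2)) {
    k <- (n - l) %/% 2
    q <- .zernike_q(k, l)
    for (m in 0:l) {
      base <- S[[l + 1]][[m + 1]] * yscale(l)   # r^l Y_lm as polynomial
      acc <- zero
      P <- base
      for (nu in 0:k) {
        acc <- acc + q[nu + 1] * P
        if (nu < k) P <- shiftz2(P)
      }
      nzidx <- which(Mod(acc) > 0)
      entries[[sprintf("%d_%d_%d", n, l, m)]] <-
        list(n = n, l = l, m = m, idx = nzidx, coef = acc[nzidx])
    }
  }
  out <- list(N = N, d = d, entries = entries)
  .zernike_env[[key]] <- out
  out
}

#' 3D Zernike moments of a voxel grid
#'
#' Computes Omega_nl^m for all n <= N, (n - l) even, |m| <= l, via
#' geometric-moment contraction. The grid must be unit-ball normalised
#' (no mass outside radius 1).
#'
#' @param grid a \code{voxel_grid}.
#' @param N maximum order (default 20).
#' @return object of class \code{"moment_set"}: data.frame with columns
#'   \code{n}, \code{l}, \code{m}, \code{value} (complex), plus attributes
#'   \code{N} and \code{channel}. Conjugation symmetry
#'   Omega_{n,l,-m} = (-1)^m conj(Omega_{n,l,m}) holds by construction.
#' @export
zernike_moments <- function(grid, N = 20L) {
  stopifnot(inherits(grid, "voxel_grid"))
  M <- grid$M
  ax <- .voxel_axis(M)
  nz <- which(grid$values > 0, arr.ind = TRUE)
  if (nrow(nz) == 0) {
    tab <- .zernike_table(N)
    nlm <- do.call(rbind, lapply(tab$entries, function(e)
      data.frame(n = e$n, l = e$l, m = e$m)))
    ms <- .expand_moments(nlm, complex(real = numeric(nrow(nlm))), N,
                          grid$channel)
    return(ms)
  }
  x <- ax[nz[, 1]]; y <- ax[nz[, 2]]; z <- ax[nz[, 3]]
  rr <- sqrt(x^2 + y^2 + z^2)
  if (any(rr > 1 + 1e-9))
    stop("grid not unit-ball normalised: mass at radius ", max(rr))
  f <- grid$values[nz]
  dV <- (2 / M)^3
  d <- N + 1L
  # geometric moments G[p+1, q+1, r+1] = sum f x^p y^q z^r
  Px <- outer(x, 0:N, `^`); Py <- outer(y, 0:N, `^`); Pz <- outer(z, 0:N, `^`)
  G <- array(0, c(d, d, d))
  for (p in 0:N) {
    w <- f * Px[, p + 1]
    G[p + 1, , ] <- crossprod(Py, w * Pz)
  }
  Gflat <- as.vector(G)
  tab <- .zernike_table(N)
  vals <- vapply(tab$entries, function(e)
    sum(Conj(e$coef) * Gflat[e$idx]), complex(1))
  nlm <- do.call(rbind, lapply(tab$entries, function(e)
    data.frame(n = e$n, l = e$l, m = e$m)))
  vals <- vals * (3 / (4 * pi)) * dV
  .expand_moments(nlm, vals, N, grid$channel)
}

# fill in m < 0 via conjugation symmetry and package as moment_set
.expand_moments <- function(nlm, vals, N, channel) {
  neg <- nlm[nlm$m > 0, , drop = FALSE]
  negvals <- vals[nlm$m > 0]
  ms <- rbind(nlm, transform(neg, m = -m))
  allvals <- c(vals, (-1)^neg$m * Conj(negvals))
  out <- data.frame(n = ms$n, l = ms$l, m = ms$m)
  out$value <- allvals
  out <- out[order(out$n, out$l, out$m), ]
  rownames(out) <- NULL
  attr(out, "N") <- N
  attr(out, "channel") <- channel
  class(out) <- c("moment_set", "data.frame")
  out
}

#' Rotation-invariant Zernike descriptor from a moment set
#'
#' F_nl = sqrt(sum_m |Omega_nl^m|^2): the per-(n, l) rotational norm,
#' invariant under any 3D rotation of the input field.
#'
#' @param moments a \code{moment_set}.
#' @return object of class \code{"zernike_descriptor"}: named numeric
#'   vector (names "n_l"), attributes \code{N} and \code{channel}.
#' @export
zernike_invariants <- function(moments) {
  stopifnot(inherits(moments, "moment_set"))
  key <- paste(moments$n, moments$l, sep = "_")
  ssq <- tapply(Mod(moments$value)^2, key, sum)
  ord <- order(as.integer(sub("_.*", "", names(ssq))),
               as.integer(sub(".*_", "", names(ssq))))
  out <- sqrt(ssq[ord])
  attr(out, "N") <- attr(moments, "N")
  attr(out, "channel") <- attr(moments, "channel")
  class(out) <- "zernike_descriptor"
  out
}

#' Euclidean distance between two Zernike descriptors
#'
#' @param d1,d2 \code{zernike_descriptor}s of the same order and channel.
#' @return non-negative scalar; 0 iff the descriptors are identical.
#' @export
descriptor_distance <- function(d1, d2) {
  if (!identical(attr(d1, "N"), attr(d2, "N")))
    stop("descriptors have different orders")
  if (!identical(attr(d1, "channel"), attr(d2, "channel")))
    stop("descriptors have different channels")
  sqrt(sum((as.numeric(d1) - as.numeric(d2))^2))
}

#' One-call shape descriptor of a region
#'
#' @inheritParams voxelize_shape
#' @param N Zernike order.
#' @return a \code{zernike_descriptor} (channel "shape").
#' @export
shape_descriptor <- function(frame, top, sel = NULL, M = 64L, N = 20L,
                             probe = 0.14) {
  zernike_invariants(zernike_moments(
    voxelize_shape(frame, top, sel, M = M, probe = probe), N = N))
}
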