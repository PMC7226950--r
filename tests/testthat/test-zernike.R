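# 3D Zernike moments, invariants and voxelization.

# Compact asymmetric blob: 8 overlapping carbon spheres. Asymmetric enough
# that higher-order invariants are non-trivial, compact enough that binary
# voxelization aliasing stays small under rotation.
.blob <- function() {
  xyz <- rbind(c(0, 0, 0), c(0.25, 0, 0), c(0.45, 0.1, 0),
               c(0.1, 0.3, 0.05), c(-0.15, 0.15, 0.2), c(0.3, 0.25, 0.25),
               c(0.05, -0.2, 0.15), c(-0.1, 0.05, -0.25))
  list(top = tiny_topology(nrow(xyz)), xyz = xyz)
}

test_that("voxel_grid validates shape and values", {
  expect_error(voxel_grid(array(0, c(4, 4, 5))), "cubic")
  expect_error(voxel_grid(array(-1, c(4, 4, 4))), ">= 0")
  g <- voxel_grid(array(1, c(4, 4, 4)))
  expect_equal(g$M, 4L)
})

test_that("voxelize_shape normalises into the unit ball and is scale-free", {
  b <- .blob()
  g <- voxelize_shape(b$xyz, b$top, M = 32)
  ax <- tcrdyn:::.voxel_axis(32)
  nz <- which(g$values > 0, arr.ind = TRUE)
  r <- sqrt(ax[nz[, 1]]^2 + ax[nz[, 2]]^2 + ax[nz[, 3]]^2)
  # all mass inside the unit ball, reaching out to ~ ball_fill
  expect_lt(max(r), 1)
  expect_gt(max(r), 0.5)
  # uniform physical rescaling (and radii with it) changes nothing
  g2 <- voxelize_shape(2 * b$xyz, b$top, M = 32,
                       radii = 2 * tcrdyn:::.default_radii, probe = 0.28)
  expect_identical(g$values, g2$values)
  expect_error(voxelize_shape(b$xyz, b$top, sel = integer(0)), "empty")
})

test_that("surface mask of a full cube is exactly the boundary shell", {
  vals <- array(1, c(5, 5, 5))
  surf <- tcrdyn:::.surface_mask(vals)
  expect_equal(sum(surf), 125L - 27L)
  expect_false(surf[3, 3, 3])
  expect_true(all(surf[1, , ]))
})

test_that("moments of a centred ball are analytic: only l = 0 survives", {
  M <- 48
  ax <- tcrdyn:::.voxel_axis(M)
  R <- 0.7
  vals <- array(0, c(M, M, M))
  for (k in seq_len(M))
    vals[, , k] <- outer(ax^2, ax^2, `+`) + ax[k]^2 <= R^2
  mom <- zernike_moments(voxel_grid(vals), N = 8)
  # Omega_000 = (3/4pi) * volume of the ball
  v000 <- mom$value[mom$n == 0 & mom$l == 0 & mom$m == 0]
  # binary voxelization converges to the analytic volume as O(1/M)
  expect_equal(Re(v000), (3 / (4 * pi)) * (4 / 3) * pi * R^3,
               tolerance = 1e-2)
  expect_lt(abs(Im(v000)), 1e-12)
  inv <- zernike_invariants(mom)
  l_of <- as.integer(sub(".*_", "", names(inv)))
  expect_gt(max(inv[l_of == 0]), 0.1)
  # discretization on a cubic grid leaks only tiny non-spherical terms
  expect_lt(max(inv[l_of > 0]), 5e-3 * max(inv))
})

test_that("moments match direct basis integration on a random grid", {
  M <- 16
  ax <- tcrdyn:::.voxel_axis(M)
  set.seed(61)
  vals <- array(0, c(M, M, M))
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  inside <- r2 <= 0.7^2
  vals[inside] <- stats::runif(sum(inside)) < 0.4
  g <- voxel_grid(vals)
  mom <- zernike_moments(g, N = 6)
  for (n in 0:6) for (l in seq(n %% 2, n, by = 2)) for (m in 0:l) {
    want <- zernike_moment_direct(g, n, l, m)
    got <- mom$value[mom$n == n & mom$l == l & mom$m == m]
    expect_equal(got, want, tolerance = 1e-6,
                 label = sprintf("Omega(%d,%d,%d)", n, l, m))
  }
})

test_that("conjugation symmetry holds across the full moment set", {
  b <- .blob()
  mom <- zernike_moments(voxelize_shape(b$xyz, b$top, M = 32), N = 10)
  pos <- mom[mom$m > 0, ]
  for (i in seq_len(nrow(pos))) {
    neg <- mom$value[mom$n == pos$n[i] & mom$l == pos$l[i] &
                       mom$m == -pos$m[i]]
    expect_equal(neg, (-1)^pos$m[i] * Conj(pos$value[i]), tolerance = 1e-12)
  }
})

test_that("shape invariants are rotation-invariant within 1 percent", {
  b <- .blob()
  d0 <- shape_descriptor(b$xyz, b$top, M = 64, N = 20)
  norm0 <- sqrt(sum(as.numeric(d0)^2))
  set.seed(62)
  for (i in 1:5) {
    R <- rotation_matrix(stats::runif(1, 0, 2 * pi),
                         stats::runif(1, 0, pi),
                         stats::runif(1, 0, 2 * pi))
    dR <- shape_descriptor(b$xyz %*% t(R), b$top, M = 64, N = 20)
    expect_lt(descriptor_distance(d0, dR) / norm0, 0.01)
  }
})

test_that("descriptor distance separates shapes and validates inputs", {
  b <- .blob()
  d1 <- shape_descriptor(b$xyz, b$top, M = 32, N = 8)
  expect_equal(descriptor_distance(d1, d1), 0)
  # an elongated variant is measurably different
  stretched <- b$xyz %*% diag(c(2.5, 1, 1))
  d2 <- shape_descriptor(stretched, b$top, M = 32, N = 8)
  expect_gt(descriptor_distance(d1, d2), 1e-3)
  d3 <- shape_descriptor(b$xyz, b$top, M = 32, N = 6)
  expect_error(descriptor_distance(d1, d3), "orders")
  attr(d2, "channel") <- "electrostatics+"
  expect_error(descriptor_distance(d1, d2), "channels")
})

test_that("electrostatic channels split surface potential by sign", {
  b <- .blob()
  top_pos <- set_nonbonded_params(b$top, charge = 1)
  el <- voxelize_electrostatics(b$xyz, top_pos, M = 32)
  expect_gt(sum(el$positive$values), 0)
  expect_equal(sum(el$negative$values), 0)
  # a +/- dipole populates both channels
  q <- c(1, 1, 1, 1, -1, -1, -1, -1)
  top_dip <- b$top; top_dip$atoms$charge <- q
  el2 <- voxelize_electrostatics(b$xyz, top_dip, M = 32)
  expect_gt(sum(el2$positive$values), 0)
  expect_gt(sum(el2$negative$values), 0)
  # values live only on surface voxels of the shape grid
  shp <- voxelize_shape(b$xyz, b$top, M = 32)
  surf <- tcrdyn:::.surface_mask(shp$values)
  expect_true(all(el2$positive$values[!surf] == 0))
  # channels carry through to comparable descriptors
  dp <- zernike_invariants(zernike_moments(el2$positive, N = 8))
  expect_equal(attr(dp, "channel"), "electrostatics+")
  # no charges and no table errors out
  expect_error(voxelize_electrostatics(b$xyz, b$top, M = 32),
               "no charge source")
})

test_that("an external potential table overrides the Coulomb fallback", {
  b <- .blob()
  # constant negative potential everywhere -> only the negative channel
  pot <- data.frame(x = 0, y = 0, z = 0, phi = -5)
  el <- voxelize_electrostatics(b$xyz, b$top, potential = pot, M = 32)
  expect_equal(sum(el$positive$values), 0)
  surf_n <- sum(el$negative$values > 0)
  expect_gt(surf_n, 0)
  expect_true(all(el$negative$values[el$negative$values > 0] == 5))
})
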