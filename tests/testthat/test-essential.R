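# Essential dynamics: covariance, spectra, projections, common subspaces.

test_that("covariance of closed-form fixtures", {
  top <- tiny_topology(3)
  ref <- matrix(stats::rnorm(9), 3, 3)
  # static ensemble -> zero matrix
  ens0 <- ensemble(top, array(rep(ref, 3), c(3, 3, 3)))
  expect_true(all(covariance_matrix(ens0, fit = FALSE) == 0))
  # two frames +/- d on one coordinate -> variance d^2 there
  d <- 0.3
  f1 <- ref; f1[2, 1] <- f1[2, 1] + d
  f2 <- ref; f2[2, 1] <- f2[2, 1] - d
  ens1 <- ensemble(top, array(c(f1, f2), c(3, 3, 2)))
  C <- covariance_matrix(ens1, fit = FALSE)
  expect_equal(C[4, 4], d^2, tolerance = 1e-12)
  expect_equal(sum(abs(C)) - abs(C[4, 4]), 0, tolerance = 1e-12)
})

test_that("diagonalize: spectrum, reconstruction, validation", {
  expect_error(diagonalize(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
  # diagonal input -> sorted diagonal
  D <- diag(c(2, 5, 1))
  ss <- diagonalize(D)
  expect_equal(ss$values, c(5, 2, 1))
  # rank-1
  v <- qr.Q(qr(matrix(stats::rnorm(12), 12, 1)))
  ss1 <- diagonalize(3 * tcrossprod(v))
  expect_equal(ss1$values[1], 3, tolerance = 1e-10)
  expect_lt(max(abs(ss1$values[-1])), 1e-10)
  # random PSD: orthonormality, trace identity, reconstruction
  set.seed(8)
  A <- matrix(stats::rnorm(144), 12, 12)
  C <- crossprod(A) / 12
  ss2 <- diagonalize(C)
  expect_equal(crossprod(ss2$vectors), diag(12), tolerance = 1e-8)
  expect_equal(sum(ss2$values), sum(diag(C)), tolerance = 1e-10)
  expect_equal(ss2$vectors %*% diag(ss2$values) %*% t(ss2$vectors), C,
               tolerance = 1e-8)
  # eigenvalues match a characteristic-polynomial root oracle
  pts <- seq(-1, max(ss2$values) + 1, length.out = 13)
  dets <- vapply(pts, function(x) det(C - x * diag(12)), 1)
  coefs <- solve(outer(pts, 0:12, `^`), dets)
  roots <- sort(Re(polyroot(coefs)), decreasing = TRUE)
  # the Vandermonde/polyroot oracle itself carries ~1e-5 noise
  expect_equal(ss2$values, roots, tolerance = 1e-4)
})

test_that("variance_fraction covers flat, rank-1 and planted spectra", {
  flat <- diagonalize(diag(rep(2, 6)))
  expect_equal(variance_fraction(flat, 1), 1 / 6)
  r1 <- diagonalize(5 * tcrossprod(qr.Q(qr(matrix(stats::rnorm(6), 6, 1)))))
  expect_equal(variance_fraction(r1, 1), 1.0, tolerance = 1e-12)
  zero <- diagonalize(matrix(0, 3, 3))
  expect_warning(vf <- variance_fraction(zero, 1), "zero")
  expect_equal(vf, 0)
})

test_that("projection variance equals the eigenvalue; mean maps to origin", {
  toy <- make_toy_complex(c(groove = 12, Valpha = 4, Vbeta = 4,
                            Calpha = 4, Cbeta = 4), seed = 9)
  top <- toy$topology
  n3 <- 3 * n_atoms(top)
  set.seed(10)
  V <- qr.Q(qr(matrix(stats::rnorm(n3 * 2), n3, 2)))
  ens <- sample_ensemble(top, get_frame(toy$ensemble, 1),
                         mode_spec(V, c(0.4, 0.2), epsilon = 1e-4),
                         n_frames = 500, seed = 11)
  ss <- essential_dynamics(ens, fit = FALSE)
  proj <- project_ensemble(ens, ss, k = 3)
  nt <- nrow(proj)
  for (k in 1:3) {
    pk <- proj[[paste0("pc", k)]]
    expect_equal(mean((pk - mean(pk))^2), ss$values[k],
                 tolerance = 1e-6 * max(ss$values))
  }
  # the mean structure projects to the origin
  ens_mean <- ensemble(top, ss$mean)
  pm <- project_ensemble(ens_mean, ss, k = 2)
  expect_equal(unlist(pm[, c("pc1", "pc2")]), c(pc1 = 0, pc2 = 0),
               tolerance = 1e-10)
  # frame = mean + c v1 projects to (c, 0)
  cc <- 0.37
  frame1 <- ss$mean + matrix(ss$vectors[, 1] * cc, ncol = 3, byrow = TRUE)
  p1 <- project_ensemble(ensemble(top, frame1), ss, k = 2)
  expect_equal(p1$pc1, cc, tolerance = 1e-10)
  expect_equal(p1$pc2, 0, tolerance = 1e-10)
})

test_that("superposed covariance keeps the trace identity and PSD-ness", {
  ens <- random_ensemble(8, 60, seed = 12)
  C <- covariance_matrix(ens, fit = TRUE)
  ss <- diagonalize(C)
  expect_equal(sum(ss$values), sum(diag(C)), tolerance = 1e-8)
  expect_true(all(ss$values >= 0))
  proj <- project_ensemble(ens, ss, k = 2)
  expect_equal(mean((proj$pc1 - mean(proj$pc1))^2), ss$values[1],
               tolerance = 1e-6 * ss$values[1])
})

test_that("combined subspace separates systems that differ in mean", {
  top <- tiny_topology(6)
  set.seed(13)
  ref <- matrix(stats::rnorm(18), 6, 3)
  n3 <- 18
  V <- qr.Q(qr(matrix(stats::rnorm(n3 * 2), n3, 2)))
  spec <- mode_spec(V, c(0.01, 0.005))
  ensA <- sample_ensemble(top, ref, spec, 300, seed = 14)
  # identical ensembles -> identical projections, overlap 1
  cs0 <- combined_subspace(list(a = ensA, b = ensA), fit = FALSE)
  expect_equal(cs0$projections$a$pc1, cs0$projections$b$pc1)
  expect_equal(subspace_overlap(cs0$projections$a, cs0$projections$b), 1.0)
  # means differing along one direction -> eigenvector 1 aligned with it,
  # clusters separate, overlap ~ 0
  shift_dir <- c(1, 0, 0)
  shift <- matrix(shift_dir, 6, 3, byrow = TRUE) * 3
  ensB <- ensA
  ensB$coords <- ensA$coords + array(rep(shift, n_frames(ensA)),
                                     c(6, 3, n_frames(ensA)))
  cs <- combined_subspace(list(a = ensA, b = ensB), fit = FALSE)
  v1 <- matrix(cs$subspace$vectors[, 1], ncol = 3, byrow = TRUE)
  dir_unit <- rep(shift_dir, 6) / sqrt(6)
  align <- abs(sum(cs$subspace$vectors[, 1] * dir_unit))
  expect_gt(align, 0.99)
  expect_lt(subspace_overlap(cs$projections$a, cs$projections$b), 0.05)
  # disjoint-mode systems separate more than same-mode systems
  V2 <- qr.Q(qr(cbind(V, matrix(stats::rnorm(n3 * 2), n3, 2))))[, 3:4]
  ensC <- sample_ensemble(top, ref, mode_spec(V2, c(0.01, 0.005)),
                          300, seed = 15)
  cs_same <- combined_subspace(list(a = ensA, b = ensA), fit = FALSE)
  cs_diff <- combined_subspace(list(a = ensA, b = ensC), fit = FALSE)
  ov_same <- subspace_overlap(cs_same$projections$a, cs_same$projections$b)
  ov_diff <- subspace_overlap(cs_diff$projections$a, cs_diff$projections$b)
  expect_gt(ov_same, ov_diff)
})

test_that("combined subspace rejects unequal atom counts, names systems", {
  e1 <- random_ensemble(5, 10, seed = 16)
  e2 <- random_ensemble(6, 10, seed = 17)
  expect_error(combined_subspace(list(small = e1, big = e2)),
               "unequal atom counts.*small=15|small")
})

test_that("subspace_overlap matches a Monte-Carlo grid-occupancy estimate", {
  set.seed(18)
  mkproj <- function(dx, n = 4000) {
    d <- data.frame(frame = 1:n, system = "x",
                    pc1 = stats::rnorm(n) + dx, pc2 = stats::rnorm(n))
    class(d) <- c("projection2d", "data.frame")
    d
  }
  a <- mkproj(0); b <- mkproj(2)
  got <- subspace_overlap(a, b, n_grid = 50)
  # independent re-count of shared occupied cells on the same raster
  xs <- range(c(a$pc1, b$pc1)); ys <- range(c(a$pc2, b$pc2))
  key <- function(p) unique(paste(
    pmin(pmax(ceiling((p$pc1 - xs[1]) / diff(xs) * 50), 1), 50),
    pmin(pmax(ceiling((p$pc2 - ys[1]) / diff(ys) * 50), 1), 50)))
  ka <- key(a); kb <- key(b)
  expect_equal(got, length(intersect(ka, kb)) / length(union(ka, kb)),
               tolerance = 1e-12)
  # far-separated clouds are disjoint
  expect_equal(subspace_overlap(mkproj(0), mkproj(100)), 0)
})
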