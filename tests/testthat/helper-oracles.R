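# Independent brute-force oracles and small fixture builders shared by the
# test files. Everything here deliberately uses the slowest, most literal
# formulation available so it stays independent of the package kernels.

# N-atom, one-residue-per-atom topology for numeric fixtures
tiny_topology <- function(n, chain = "A", name = "CA", element = "C") {
  topology(data.frame(id = seq_len(n), name = name, element = element,
                      resno = seq_len(n), resname = "ALA", chain = chain,
                      stringsAsFactors = FALSE))
}

random_ensemble <- function(n_atoms, n_frames, seed = 1, sd = 0.3) {
  set.seed(seed)
  top <- tiny_topology(n_atoms)
  coords <- array(stats::rnorm(n_atoms * 3 * n_frames, sd = sd),
                  c(n_atoms, 3, n_frames))
  ensemble(top, coords)
}

rotation_matrix <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                             0, 0, 1), 3, 3, byrow = TRUE)
  Rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), -sin(t),
                             0, sin(t), cos(t)), 3, 3, byrow = TRUE)
  Rz(a) %*% Rx(b) %*% Rz(c)
}

# Eq.-style double loops --------------------------------------------------

brute_rmsd <- function(coords_t, ref) {
  n <- nrow(ref)
  acc <- 0
  for (i in seq_len(n))
    acc <- acc + sum((coords_t[i, ] - ref[i, ])^2)
  sqrt(acc / n)
}

brute_rmsf <- function(coords, ref) {
  # coords: N x 3 x T; per-atom sqrt mean squared deviation from ref
  n <- dim(coords)[1]; nt <- dim(coords)[3]
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (t in seq_len(nt))
      acc <- acc + sum((coords[i, , t] - ref[i, ])^2)
    out[i] <- sqrt(acc / nt)
  }
  out
}

brute_correlation <- function(coords) {
  n <- dim(coords)[1]; nt <- dim(coords)[3]
  mu <- apply(coords, c(1, 2), mean)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0; di <- 0; dj <- 0
    for (t in seq_len(nt)) {
      a <- coords[i, , t] - mu[i, ]
      b <- coords[j, , t] - mu[j, ]
      num <- num + sum(a * b)
      di <- di + sum(a * a); dj <- dj + sum(b * b)
    }
    C[i, j] <- if (di == 0 || dj == 0) 0 else num / sqrt(di * dj)
  }
  diag(C) <- 1
  C
}

# Contact graph / centrality ----------------------------------------------

brute_edges <- function(xyz, cutoff) {
  n <- nrow(xyz)
  e <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < cutoff)
      e[[length(e) + 1]] <- c(i, j)
  }
  if (length(e)) do.call(rbind, e) else matrix(0L, 0, 2)
}

bfs_distances <- function(adj, v) {
  n <- nrow(adj)
  d <- rep(Inf, n); d[v] <- 0
  queue <- v
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    nb <- which(adj[u, ] & is.infinite(d))
    d[nb] <- d[u] + 1
    queue <- c(queue, nb)
  }
  d
}

bfs_closeness <- function(adj) {
  n <- nrow(adj)
  out <- numeric(n)
  for (v in seq_len(n)) {
    d <- bfs_distances(adj, v)[-v]
    reach <- is.finite(d)
    nc <- sum(reach) + 1
    if (nc > 1 && n > 1)
      out[v] <- ((nc - 1) / (n - 1)) * (nc - 1) / sum(d[reach])
  }
  out
}

# Nonbonded energies --------------------------------------------------------

brute_pair_energy <- function(xyz, q, sig, eps, ia, ib, cutoff,
                              f = 138.935458) {
  coul <- 0; lj <- 0
  for (i in ia) for (j in ib) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r >= cutoff) next
    coul <- coul + f * q[i] * q[j] / r
    sij <- (sig[i] + sig[j]) / 2
    eij <- sqrt(eps[i] * eps[j])
    lj <- lj + 4 * eij * ((sij / r)^12 - (sij / r)^6)
  }
  c(coulomb = coul, lj = lj)
}

# Direct Zernike basis integration (independent of the monomial route) ----

# associated Legendre P_l^m(x) with Condon-Shortley phase
assoc_legendre <- function(l, m, x) {
  pmm <- rep(1, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(1 - x * x, 0))
    fact <- 1
    for (i in seq_len(m)) {
      pmm <- -pmm * fact * somx2
      fact <- fact + 2
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  pll <- pmmp1
  for (ll in (m + 2):l) {
    pll <- ((2 * ll - 1) * x * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1; pmmp1 <- pll
  }
  pll
}

# Y_lm in the package's normalisation: integral |Y|^2 dOmega = 4 pi
ylm_direct <- function(l, m, theta, phi) {
  am <- abs(m)
  nrm <- sqrt((2 * l + 1) * exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
  base <- nrm * assoc_legendre(l, am, cos(theta)) * exp(1i * am * phi)
  if (m >= 0) base else (-1)^am * Conj(base)
}

zernike_moment_direct <- function(grid, n, l, m) {
  M <- grid$M
  ax <- -1 + (seq_len(M) - 0.5) * 2 / M
  nz <- which(grid$values > 0, arr.ind = TRUE)
  x <- ax[nz[, 1]]; y <- ax[nz[, 2]]; z <- ax[nz[, 3]]
  f <- grid$values[nz]
  r <- sqrt(x^2 + y^2 + z^2)
  theta <- acos(ifelse(r > 0, z / r, 1))
  phi <- atan2(y, x)
  k <- (n - l) %/% 2
  q <- tcrdyn:::.zernike_q(k, l)
  Rnl <- numeric(length(r))
  for (nu in 0:k) Rnl <- Rnl + q[nu + 1] * r^(2 * nu + l)
  dV <- (2 / M)^3
  (3 / (4 * pi)) * dV * sum(f * Rnl * Conj(ylm_direct(l, m, theta, phi)))
}
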