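# Nonbonded region-pair energies: Coulomb, Lennard-Jones, distributions.

.etop <- function(n, charge = 0, sigma = 0.3, epsilon = 0.5,
                  split = n %/% 2) {
  at <- data.frame(id = seq_len(n), name = "CA", element = "C",
                   resno = seq_len(n), resname = "ALA", chain = "A",
                   stringsAsFactors = FALSE)
  top <- topology(at, list(a = seq_len(split), b = (split + 1):n))
  set_nonbonded_params(top, charge = charge, sigma = sigma,
                       epsilon = epsilon)
}

test_that("unit charges 1 nm apart give +/- the Coulomb constant", {
  expect_equal(COULOMB_CONSTANT, 138.935458)
  top <- .etop(2, charge = c(1, 1), epsilon = 0)
  frame <- rbind(c(0, 0, 0), c(1, 0, 0))
  e <- pair_energy(frame, top, select_atoms(top, region = "a"),
                   select_atoms(top, region = "b"))
  expect_equal(e$coulomb, 138.935458, tolerance = 1e-12)
  expect_equal(e$lj, 0)
  top2 <- .etop(2, charge = c(1, -1), epsilon = 0)
  e2 <- pair_energy(frame, top2, select_atoms(top2, region = "a"),
                    select_atoms(top2, region = "b"))
  expect_equal(e2$coulomb, -138.935458, tolerance = 1e-12)
  expect_equal(e2$total, e2$coulomb + e2$lj)
  # dielectric scales Coulomb linearly
  e4 <- pair_energy(frame, top, select_atoms(top, region = "a"),
                    select_atoms(top, region = "b"), dielectric = 4)
  expect_equal(e4$coulomb, 138.935458 / 4, tolerance = 1e-12)
})

test_that("LJ crosses zero at r = sigma and bottoms at -epsilon", {
  top <- .etop(2, charge = 0, sigma = 0.3, epsilon = 0.5)
  sa <- select_atoms(top, region = "a"); sb <- select_atoms(top, region = "b")
  at_r <- function(r) pair_energy(rbind(c(0, 0, 0), c(r, 0, 0)),
                                  top, sa, sb)
  expect_equal(at_r(0.3)$lj, 0)
  rmin <- 2^(1 / 6) * 0.3
  expect_equal(at_r(rmin)$lj, -0.5, tolerance = 1e-12)
  # numerically verify the minimum
  expect_gt(at_r(rmin * 1.05)$lj, -0.5)
  expect_gt(at_r(rmin * 0.95)$lj, -0.5)
})

test_that("the cutoff is strict: pairs at exactly 1.2 nm contribute nothing", {
  top <- .etop(2, charge = c(1, 1), epsilon = 0)
  sa <- select_atoms(top, region = "a"); sb <- select_atoms(top, region = "b")
  e_at <- pair_energy(rbind(c(0, 0, 0), c(1.2, 0, 0)), top, sa, sb)
  expect_equal(e_at$total, 0)
  e_in <- pair_energy(rbind(c(0, 0, 0), c(1.199, 0, 0)), top, sa, sb)
  expect_gt(e_in$coulomb, 0)
})

test_that("random 50-atom frames match the brute-force double loop", {
  set.seed(81)
  for (rep in 1:5) {
    q <- stats::runif(50, -1, 1)
    sig <- stats::runif(50, 0.25, 0.4)
    eps <- stats::runif(50, 0.1, 1)
    top <- .etop(50, charge = q, sigma = sig, epsilon = eps, split = 25)
    frame <- matrix(stats::runif(150, 0, 2.5), 50, 3)
    e <- pair_energy(frame, top, select_atoms(top, region = "a"),
                     select_atoms(top, region = "b"))
    want <- brute_pair_energy(frame, q, sig, eps, 1:25, 26:50, cutoff = 1.2)
    expect_equal(e$coulomb, unname(want["coulomb"]), tolerance = 1e-10)
    expect_equal(e$lj, unname(want["lj"]), tolerance = 1e-10)
  }
})

test_that("Lorentz-Berthelot combination is applied per pair", {
  top <- .etop(2, charge = 0, sigma = c(0.2, 0.4), epsilon = c(0.25, 1))
  sa <- select_atoms(top, region = "a"); sb <- select_atoms(top, region = "b")
  sij <- 0.3; eij <- sqrt(0.25 * 1)
  r <- 0.5
  e <- pair_energy(rbind(c(0, 0, 0), c(r, 0, 0)), top, sa, sb)
  expect_equal(e$lj, 4 * eij * ((sij / r)^12 - (sij / r)^6),
               tolerance = 1e-12)
})

test_that("validation: overlap, missing parameters, clash warning", {
  top <- .etop(4)
  frame <- matrix(c(0, 0, 0, 0.005, 0, 0, 3, 3, 3, 4, 4, 4), 4, 3,
                  byrow = TRUE)
  expect_error(pair_energy(frame, top, select_atoms(top, ids = 1:3),
                           select_atoms(top, ids = 3:4)), "overlap")
  bare <- topology(top$atoms[, setdiff(names(top$atoms),
                                       c("charge", "sigma", "epsilon"))],
                   top$region_map)
  expect_error(pair_energy(frame, bare, select_atoms(bare, region = "a"),
                           select_atoms(bare, region = "b")),
               "missing nonbonded parameters")
  expect_warning(pair_energy(frame, top, select_atoms(top, ids = 1),
                             select_atoms(top, ids = 2)), "clash")
})

test_that("energy distributions: bound frames sit below unbound frames", {
  toy <- make_toy_complex(c(groove = 10, Valpha = 3, Vbeta = 3,
                            Calpha = 3, Cbeta = 3), seed = 82)
  top <- set_nonbonded_params(toy$topology, charge = 0.2, sigma = 0.3,
                              epsilon = 0.2)
  # opposite charges across the interface attract
  pep_rows <- tcrdyn:::sel_rows(top, select_atoms(top, region = "peptide"))
  top$atoms$charge[pep_rows] <- -0.2
  ref <- get_frame(toy$ensemble, 1)
  nt <- 20
  coords <- array(0, c(n_atoms(top), 3, nt))
  for (t in seq_len(nt)) {
    fr <- ref
    if (t > nt / 2)  # unbound half: pull the peptide 3 nm away
      fr[pep_rows, 3] <- fr[pep_rows, 3] + 3
    coords[, , t] <- fr
  }
  ens <- ensemble(top, coords)
  ed <- energy_distribution(ens, list(c("peptide", "groove")), bins = 10)
  expect_equal(nrow(ed$series), nt)
  expect_equal(unique(ed$series$pair), "peptide-groove")
  bound <- ed$series$total[1:(nt / 2)]
  unbound <- ed$series$total[(nt / 2 + 1):nt]
  expect_lt(mean(bound), mean(unbound))
  expect_true(all(bound < 0))
  expect_true(all(unbound == 0))  # separated beyond the 1.2 nm cutoff
  expect_equal(ed$summary$mean, mean(ed$series$total), tolerance = 1e-12)
  # the histogram mode lands in the fuller (bound-or-unbound) cluster
  expect_true(ed$summary$mode < mean(ed$series$total) ||
                abs(ed$summary$mode) < abs(min(bound)))
})

test_that("parameter tables attach by atom name", {
  at <- data.frame(id = 1:3, name = c("N", "CA", "CX"),
                   element = c("N", "C", "C"), resno = 1:3,
                   resname = "ALA", chain = "A", stringsAsFactors = FALSE)
  top <- topology(at)
  f <- tempfile(fileext = ".txt")
  writeLines(c("name charge sigma epsilon",
               "N -0.5 0.32 0.7",
               "CA 0.1 0.34 0.4"), f)
  top2 <- read_param_table(top, f)
  expect_equal(top2$atoms$charge, c(-0.5, 0.1, 0))   # CX falls back
  expect_equal(top2$atoms$sigma, c(0.32, 0.34, 0.3))
  expect_equal(top2$atoms$epsilon, c(0.7, 0.4, 0))
  writeLines(c("name charge", "N -0.5"), f)
  expect_error(read_param_table(top, f), "needs columns")
})
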