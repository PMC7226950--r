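# Core data model: topologies, ensembles, selections, file I/O, trimming.

test_that("topology enforces unique atom ids and resolvable regions", {
  at <- data.frame(id = c(1L, 1L), name = "CA", element = "C",
                   resno = 1:2, resname = "ALA", chain = "A")
  expect_error(topology(at), "unique")
  at$id <- 1:2
  expect_error(topology(at, list(bad = 99L)), "unknown atom id")
  top <- topology(at, list(peptide = 1:2))
  expect_identical(top$pep_labels, c("P1", "P2"))
})

test_that("ensemble validates frame shape and timestamps", {
  top <- tiny_topology(3)
  expect_error(ensemble(top, array(0, c(4, 3, 2))), "does not match")
  expect_error(ensemble(top, array(0, c(3, 3, 2)), times = c(1, 1)),
               "strictly increasing")
  e <- ensemble(top, array(0, c(3, 3, 2)), times = c(0, 1))
  expect_equal(n_frames(e), 2L)
})

test_that("selections compose: |A u B| + |A n B| = |A| + |B|", {
  toy <- make_toy_complex(c(groove = 30, Valpha = 8, Vbeta = 8,
                            Calpha = 8, Cbeta = 8), seed = 2)
  top <- toy$topology
  set.seed(9)
  for (rep in 1:20) {
    a <- select_atoms(top, ids = sample(top$atoms$id, sample(1:40, 1)))
    b <- select_atoms(top, ids = sample(top$atoms$id, sample(1:40, 1)))
    expect_equal(length(sel_union(a, b)$ids) + length(sel_intersect(a, b)$ids),
                 length(a$ids) + length(b$ids))
  }
  # resolution is order-preserving along topology order
  s <- select_atoms(top, chain = "A")
  expect_false(is.unsorted(match(s$ids, top$atoms$id)))
})

test_that("PDB reading converts Angstrom to nm and keeps identity", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.000   3.000   4.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       3.000   4.000   5.000  1.00  0.00           C",
    "END"), pdb)
  st <- read_structure(pdb)
  expect_equal(nrow(st$topology$atoms), 3L)
  expect_equal(get_frame(st$ensemble, 1)[2, ], c(0.2, 0.3, 0.4))
  expect_equal(st$topology$atoms$name, c("N", "CA", "C"))
})

test_that("PDB insertion codes are retained (frozen reference parse)", {
  st <- read_structure(system.file("extdata", "insertion_codes.pdb",
                                   package = "tcrdyn"))
  at <- st$topology$atoms
  # expected values computed with an independent reference parser
  expect_equal(at$resno, c(52L, 52L, 52L, 53L))
  expect_equal(at$insert, c("", "A", "B", ""))
  expect_equal(at$resname, c("ALA", "GLY", "SER", "LEU"))
  expect_equal(get_frame(st$ensemble, 1)[2, ], c(1.25, 2.10, 0.40))
  expect_equal(get_frame(st$ensemble, 1)[3, ], c(1.325, 2.275, 0.55))
})

test_that("GRO round trip preserves coordinates, box and atom order", {
  toy <- make_toy_complex(c(groove = 10, Valpha = 3, Vbeta = 3,
                            Calpha = 3, Cbeta = 3), seed = 4)
  ens <- ensemble(toy$topology, get_frame(toy$ensemble, 1),
                  box = matrix(c(8, 8, 8), 1))
  f <- tempfile(fileext = ".gro")
  write_gro(ens, f)
  back <- read_structure(f)
  expect_equal(n_atoms(back$ensemble), n_atoms(ens))
  # GRO stores %.3f nm: round trip is exact up to that quantization
  expect_lt(max(abs(get_frame(back$ensemble, 1) - get_frame(ens, 1))),
            5.01e-4)
  expect_equal(back$ensemble$box[1, ], c(8, 8, 8))
  expect_equal(back$topology$atoms$name, toy$topology$atoms$name)
})

test_that("multi-model PDB round trip: frame count and coordinates", {
  toy <- make_toy_complex(c(groove = 8, Valpha = 3, Vbeta = 3,
                            Calpha = 3, Cbeta = 3), seed = 5)
  spec <- mode_spec(diag(3 * n_atoms(toy$topology))[, 1:2],
                    c(0.02, 0.01))
  ens <- sample_ensemble(toy$topology, get_frame(toy$ensemble, 1), spec,
                         n_frames = 5, seed = 6)
  f <- tempfile(fileext = ".pdb")
  write_pdb_ensemble(ens, f)
  back <- read_trajectory(toy$topology, f, dt = 1)
  expect_equal(n_frames(back), 5L)
  expect_equal(back$coords, ens$coords, tolerance = 1e-3)
  expect_equal(back$times, 0:4)
})

test_that("read_trajectory rejects atom-count mismatches", {
  toy <- make_toy_complex(c(groove = 8, Valpha = 3, Vbeta = 3,
                            Calpha = 3, Cbeta = 3), seed = 5)
  f <- tempfile(fileext = ".pdb")
  write_pdb_ensemble(toy$ensemble, f)
  expect_error(read_trajectory(tiny_topology(4), f), "topology mismatch")
})

test_that("DCD reading agrees with an externally converted trajectory", {
  toy <- make_toy_complex(c(groove = 6, Valpha = 3, Vbeta = 3,
                            Calpha = 3, Cbeta = 3), seed = 7)
  spec <- mode_spec(diag(3 * n_atoms(toy$topology))[, 1, drop = FALSE], 0.01)
  ens <- sample_ensemble(toy$topology, get_frame(toy$ensemble, 1), spec,
                         n_frames = 4, seed = 8)
  pdbf <- tempfile(fileext = ".pdb")
  dcdf <- tempfile(fileext = ".dcd")
  write_pdb_ensemble(ens, pdbf)
  status <- system2("python",
                    c("-c", shQuote(sprintf(
                      "import mdtraj; t = mdtraj.load_pdb('%s'); t.save_dcd('%s')",
                      pdbf, dcdf))),
                    stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  # bio3d warns about the (valid) header written by other tools
  back <- suppressWarnings(read_trajectory(toy$topology, dcdf, dt = 1))
  expect_equal(n_frames(back), 4L)
  expect_equal(back$coords, ens$coords, tolerance = 2e-3)
})

test_that("trim_equilibration keeps frames at or after t_start", {
  top <- tiny_topology(2)
  ens <- ensemble(top, array(stats::rnorm(2 * 3 * 51), c(2, 3, 51)),
                  times = seq(0, 500, by = 10))
  tr <- trim_equilibration(ens, 50)
  expect_equal(range(tr$times), c(50, 500))
  expect_equal(n_frames(tr), 46L)
  expect_identical(trim_equilibration(ens, 0)$coords, ens$coords)
  expect_warning(empty <- trim_equilibration(ens, 1000), "no frames")
  expect_equal(n_frames(empty), 0L)
})

test_that("region config resolves chains and residue ranges", {
  toy <- make_toy_complex(c(groove = 20, Valpha = 5, Vbeta = 5,
                            Calpha = 5, Cbeta = 5), seed = 1)
  cfgf <- tempfile(fileext = ".yaml")
  writeLines(c("groove_half:", "  chain: A", "  resno: [1, 10]",
               "peptide:", "  chain: C", "  resno: [1, 9]"), cfgf)
  top2 <- read_region_config(toy$topology, cfgf)
  expect_length(top2$region_map$groove_half, 10L)
  expect_length(top2$region_map$peptide, 9L)
  expect_identical(top2$pep_labels, paste0("P", 1:9))
})
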