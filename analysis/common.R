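# Shared setup for the numbered analysis scripts: builds the two synthetic
# study systems (a "wild-type" and a "variant" pMHC-TCR complex) once and
# caches them under results/data/. Every script can be run standalone;
# together they form the full post-simulation workflow.

library(tcrdyn)

RESULTS <- file.path("results")
DATA <- file.path(RESULTS, "data")
dir.create(DATA, recursive = TRUE, showWarnings = FALSE)

SEED <- 2024L
N_FRAMES <- 1000L   # synthetic production segment (1 frame / ns)

build_systems <- function() {
  cache <- file.path(DATA, "systems.rds")
  if (file.exists(cache)) return(readRDS(cache))
  message("building synthetic systems (cached afterwards) ...")
  mk <- function(name, seed, amps) {
    toy <- make_toy_complex(seed = seed)        # 175-residue groove, 9-mer
    # charge-only parameters: the C-alpha clouds overlap sterically, so a
    # repulsive LJ term would be dominated by unphysical near-contacts
    top <- set_nonbonded_params(toy$topology, charge = 0.1, sigma = 0.3,
                                epsilon = 0)
    pep <- tcrdyn:::sel_rows(top, select_atoms(top, region = "peptide"))
    top$atoms$charge[pep] <- -0.1               # attractive interface
    n3 <- 3 * n_atoms(top)
    set.seed(seed + 1)
    V <- qr.Q(qr(matrix(rnorm(n3 * 3), n3, 3)))
    ens <- sample_ensemble(top, get_frame(toy$ensemble, 1),
                           mode_spec(V, amps, epsilon = 2e-4),
                           n_frames = N_FRAMES, seed = seed + 2)
    list(name = name, topology = top, ensemble = ens, modes = V,
         amplitudes = amps)
  }
  systems <- list(
    wild = mk("wild", SEED, c(0.60, 0.30, 0.10)),
    variant = mk("variant", SEED + 50L, c(0.90, 0.20, 0.05)))
  saveRDS(systems, cache)
  systems
}
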