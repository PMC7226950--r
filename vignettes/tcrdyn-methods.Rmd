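---
title: "tcrdyn: methods and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tcrdyn: methods and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tcrdyn` is a post-simulation analysis toolkit for molecular-dynamics
ensembles of peptide--MHC--T-cell-receptor (pMHC--TCR) complexes. It covers
the standard comparative workflow for such systems: fluctuation profiles,
essential dynamics with cross-system common subspaces, thresholded
cross-correlation maps, residue-contact networks, hydrogen-bond occupancy
and anchor analysis, rotation-invariant 3D Zernike descriptors of groove
shape and electrostatics, bilayer thickness maps, and region-pair
interaction energies. This vignette documents the data model, the
numerical conventions each module commits to, and what the synthetic
generators do and do not emulate.

## Data model and units

All coordinates are stored in **nanometres**; PDB files (Ångström) are
divided by 10 on read and multiplied on write. Residue and atom numbering
is 1-based. A `topology` is a data frame of atoms (id, name, element,
residue, chain, insertion code, optional nonbonded parameters) plus a
named `region_map` assigning atom ids to biological regions (`groove`,
`peptide`, `Valpha`, ...). An `ensemble` binds a topology to an
`N x 3 x T` coordinate array with strictly increasing timestamps in ns and
an optional per-frame box.

Supported file formats are PDB (single- and multi-model), GRO and DCD.
XTC is not read: no installed R-level reader exists for the format, and
re-implementing its compression scheme is out of scope; convert XTC to DCD
or multi-model PDB upstream.

```{r}
library(tcrdyn)
st  <- read_structure("complex.pdb")
top <- read_region_config(st$topology, "regions.yaml")
ens <- read_trajectory(top, "trajectory.dcd", dt = 0.1)  # ns per frame
ens <- trim_equilibration(ens, 50)  # discard the first 50 ns
```

## Superposition, RMSD, RMSF

Least-squares superposition uses the Kabsch algorithm (SVD with
determinant correction, so only proper rotations are returned). Degenerate
selections (< 3 atoms, or collinear) are rejected. RMSD is the plain
per-frame root-mean-square deviation from a reference frame, optionally
after fitting. RMSF supports two references: the initial frame (deviation
from the start) or the time-average structure (true fluctuation; always
the smaller of the two).

## Essential dynamics

The positional covariance matrix uses the **population normalisation 1/T**
(not 1/(T-1)). This is deliberate: with the matching projection
convention, the sample variance of the projection onto eigenvector *k*
equals the eigenvalue exactly, which the tests assert to 1e-6 relative.
Fitting follows an iterative mean-refinement scheme (fit to frame 1, then
twice to the running mean); the final fit target and mean are stored in
the subspace object so that `project_ensemble()` can reproduce exactly the
frame treatment used to build the covariance.

Common subspaces for cross-system comparison concatenate trajectories of
systems with **equal atom counts** and diagonalise the joint covariance;
every frame carries equal weight, so systems contribute in proportion to
their frame counts. The 2D projection overlap is the Jaccard index of
occupied cells on a common 50 x 50 raster over the joint bounding box.

## Cross-correlation maps

The dynamic cross-correlation matrix (DCCM) entry for atoms *i*, *j* is
the normalised inner product of their 3D displacement vectors. Atoms with
zero variance yield 0 with a warning rather than NaN. Classification is
intentionally literal and asymmetric, matching common practice for
pMHC-TCR maps: **correlated iff value > 0.75** (strict) and
**anticorrelated iff value in [-1, -0.25]** (closed); everything else is
neutral. Boundary behaviour is pinned by tests at 0.75 and -0.25 exactly.

## Contact networks

Residues are nodes; an edge joins two residues whose C-alpha atoms lie
**strictly closer than 0.6 nm** (a distance of exactly 0.6 nm is not an
edge). Closeness centrality uses the Wasserman--Faust component scaling,
`((n_c - 1)/(n - 1)) * (n_c - 1) / sum(d)`, so values stay in [0, 1] and
remain comparable across frames in which the graph disconnects. Metrics
are accumulated over ~100 evenly spaced frames by default (deterministic;
uniform random sampling with a seed is available).

## Hydrogen bonds and anchors

A hydrogen bond requires donor--acceptor distance <= 0.35 nm and, when the
donor has an attached hydrogen in the topology, an H--D--A angle (at the
donor) <= 30 degrees. The attached hydrogen is identified positionally:
the next atom in file order within the same residue with element H.
Topologies without hydrogens fall back to the distance criterion alone,
flagged per row. Occupancy is the fraction of frames in which at least one
bond connects a given (partner residue, peptide position) pair.
`anchor_analysis()` checks the canonical class-I pattern: persistent
groove bonds at P1--P2 (N-terminal anchor) and P(n-1)--Pn (C-terminal
anchor), plus central TCR contacts at P4--P5.

## 3D Zernike descriptors

A region is voxelized as a union of element-radius spheres inflated by a
0.14 nm probe, centred on its centroid and isotropically scaled so the
outermost sphere surface sits at radius **0.7** of the unit ball (the
margin avoids truncating basis support). Defaults are a **64^3 grid** and
**order N = 20**, the usual operating point for molecular 3DZD at this
resolution. Moments are computed by expanding each basis function into
Cartesian monomials (Racah solid-harmonic recursions; Novotni--Klein
radial coefficients evaluated in log-gamma space) and contracting against
the grid's geometric moments; negative m follows from conjugation
symmetry. The descriptor `F_nl = sqrt(sum_m |Omega_nlm|^2)` is rotation
invariant; tests bound the residual variation under random rotations of a
compact blob below 1% (the residual is binary-voxelization aliasing, which
grows for sparse, multi-cluster geometries). Electrostatics channels
assign surface voxels (occupied voxels with an empty 6-neighbour) the
local potential, split into max(phi, 0) and max(-phi, 0) grids; the
potential comes from an external table or an internal Coulomb sum.

## Membrane thickness

Headgroups are split into leaflets by the sign of z relative to their mean
(midplane). Thickness follows the GridMAT-style recipe on a **100 x 100**
lateral grid: per cell, the z of the nearest upper-leaflet headgroup minus
the z of the nearest lower one, with minimum-image lateral distances when
a box is present. `thickness_comparison()` contrasts first- and
second-half means to expose drift.

## Interaction energies

Region-pair energies are descriptive statistics, not forces: Coulomb
(f = 138.935458 kJ mol^-1 nm e^-2, uniform dielectric) plus Lennard-Jones
with Lorentz--Berthelot combination, summed over cross pairs with
**r < 1.2 nm** (plain cutoff, no Ewald, no 1-4 exclusions: analysed
regions are never covalently bonded to each other). Pairs below 0.01 nm
trigger a clash warning but are still evaluated.

## Synthetic generators and ground truth

Every generator is a pure function of (spec, seed). They emulate the
*statistical structure* the analyses consume, not molecular physics:

- `make_toy_complex()` lays out the six canonical regions as segregated
  C-alpha clouds (default 175-residue groove, 9-mer peptide).
- `sample_ensemble()` draws Gaussian frames with covariance
  `V diag(a) V' + eps I`, **pre-aligned** (no global drift), so
  covariance analyses recover the planted spectrum with `fit = FALSE`.
- `sample_correlated_pair()` plants an exact inter-region displacement
  correlation rho.
- `make_hbond_trajectory()` produces donor/H/acceptor triplets that
  satisfy the geometric criteria in exactly the Bernoulli-sampled frames,
  so realized occupancy is recovered exactly.
- `make_bilayer()` places headgroups on analytic sinusoidal leaflet
  surfaces (`bilayer_surfaces()` exposes the ground truth per cell).

Problem sizes in the tests and the `analysis/` scripts (thousands of
frames, hundreds of atoms) are the package's own desk-scale choices;
the machinery itself is size-agnostic.

## Orchestration

`run_study()` executes all configured stages per system from a single
declarative `study_config()`, writes flat CSV/JSON outputs per system plus
a `manifest.json` (written atomically), and isolates stage failures: a
failing stage is recorded while the rest proceed. Identical configurations
and seeds give byte-identical outputs apart from the wall-time entry in
the manifest.
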