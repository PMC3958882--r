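# dimermd

Trajectory analysis for dimeric helical proteins that hinge between
**closed** and **open** conformations — the 14-3-3 adaptor-protein family
being the archetype. Given a molecular-dynamics trajectory (multi-model
PDB), a tabular per-atom topology, and a helix annotation mapping segments
A–I to residue ranges per monomer, the package computes the observables
such a study reports, for structural bioinformaticians and molecular
modellers who want the analysis layer reusable and tested rather than
re-scripted per project.

## What it computes

**Conformational state.** The state metric is the distance between the
mass center of the dimerization base (helices A–D of both monomers) and
each monomer's top-helix (G–I) mass center:
`d_m = |COM(A–D, both chains) − COM(G–I, monomer m)|`. A monomer is
*closed* for `d < 35 Å`, *open* for `d > 37 Å`, *intermediate* between —
thresholds are configurable defaults. Supporting series: top–top
distance, backbone RMSD (Kabsch), Cα RMSF about the iteratively aligned
mean structure, and least-squares trend fits.

**Secondary structure.** A DSSP-style helix/turn assignment from the
Kabsch–Sander backbone hydrogen-bond energy
`E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` (bond if
`E < −0.5 kcal/mol`; two consecutive i→i+4 turns ⇒ α-helix).

**Interactions.** Hydrogen bonds (present iff `d_DA ≤ 3.5 Å` and
`∠D–H···A ≥ 120°`) with per-trajectory occupancies; hydrophobic contacts
between nonpolar heavy atoms (3.9 Å cutoff) with populations; minimum
side-chain distance series.

**MM-GBSA energetics.** Per snapshot,

```
G_total = H_gas + G_solvation,   H_gas = E_vdW + E_ele,
G_solvation = G_pol + G_nonpol,  G_nonpol = γ·SASA + β   (γ = 0.005, β = 0)
```

with HCT (igb=1-style) generalized-Born polar solvation (ε_w = 78.5) and
deterministic Shrake–Rupley SASA. Monomer–monomer binding energies use
the single-trajectory scheme `ΔG = G(AB) − G(A) − G(B)` (bonded terms
cancel), decomposed per residue as
`ΔG_residue = ΔE_vdW + ΔE_ele + ΔG_pol + ΔG_nonpol` with exact component
conservation, plus a quasi-harmonic configurational entropy.

**Clustering.** Vectorized all-pairs Kabsch RMSD matrices,
average-linkage clustering with populations, and nearest-to-center
representative structures.

**Synthetic data.** A generator of C2-symmetric toy dimer trajectories
with planted ground truth (state schedule, H-bond/contact occupancies,
toy force-field parameters) used throughout the tests.

## Worked example

```r
library(dimermd)

cfg <- scenario_config(
  n_frames = 300, noise_sigma = 0.3,
  schedule = c(rep(0, 100), seq(0, 1, length.out = 100), rep(1, 100)),
  planted_hbonds = data.frame(donor_res = 35, acceptor_res = 110,
                              occupancy = 0.9),
  seed = 42)
sim <- generate_trajectory(cfg)

ss <- state_series(sim$trajectory, sim$helix_map, sim$topology)
round(table(ss$label_A) / nrow(ss), 3)
#>       closed intermediate         open
#>        0.417        0.083        0.500
linear_trend(ss$time_ps, ss$d_A, window = c(100, 199))$slope
#> 0.0808   # Å/ps during the opening phase

hb <- sim$ground_truth$hbonds
hbond_occupancy(sim$trajectory, hb$donor_atom, hb$hydrogen_atom,
                hb$acceptor_atom)
#> hbond 211-212...663: occupancy 91.33% (mean d 3.17 A, mean angle 180.0 deg)

bb <- which(sim$topology$name %in% c("N", "CA", "C", "O"))
cl <- average_linkage_cluster(pairwise_rmsd_matrix(sim$trajectory, bb),
                              n_clusters = 3)
cl
#> 3 clusters over 300 frames
#>   cluster 1: 40.33%  representative frame 78
#>   cluster 2: 19.00%  representative frame 150
#>   cluster 3: 40.67%  representative frame 284
```

The trajectory spends 100 frames closed (d = 33 Å), ramps open over 100,
and stays open (41 Å): the label fractions, the positive opening slope,
the ~90% planted bond occupancy, and the closed/transition/open cluster
split all read off the planted ground truth. `run_pipeline()` drives the
same analyses from a YAML config and writes CSV tables, a run log, and a
JSON summary (see `inst/cli/dimermd-cli.R` for the command-line wrapper
with `simulate`/`state`/`mmgbsa`/… subcommands).

## Layout

- `R/` — implementation (trajectory/topology/helix-map I/O, geometry and
  state metric, DSSP subset, interactions, energetics, clustering,
  synthetic generator, pipeline).
- `tests/testthat/` — unit, property and acceptance suites (oracles:
  closed forms, brute-force rotation sampling, Monte-Carlo quadrature,
  planted ground truth, a frozen Kabsch–Sander reference assignment).
- `vignettes/dimermd-methods.Rmd` — the models, assumptions, parameter
  meanings, numerical choices, and known limitations.
- `scripts/acceptance.R` — the reproduction script above.
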