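---
title: "Models and methods behind dimermd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dimermd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimermd)
```

# Scope

`dimermd` is the analysis layer for molecular-dynamics studies of dimeric
all-alpha proteins that hinge between a *closed* and an *open* conformation
-- the 14-3-3 family being the motivating system, where each monomer's nine
antiparallel helices form an amphipathic groove, helices A-D build the
dimerization base, E-F the hinge, and G-I the mobile top. The package does
not run dynamics; it consumes saved trajectories (multi-model PDB plus a
tabular per-atom topology and a helix annotation) and computes the derived
observables such a study reports: conformational-state series, RMSD/RMSF,
secondary-structure stability, hydrogen-bond and hydrophobic-contact
populations, RMSD clustering, and MM-GBSA energetics with per-residue
decomposition.

# The open/closed state metric

For each frame, the metric is the distance between the mass center of the
dimerization base -- all atoms of helices A-D of *both* monomers jointly --
and the mass center of one monomer's top helices G-I. A monomer is labeled
**closed** below 35 Angstrom and **open** above 37 Angstrom; the band in
between is reported as **intermediate** rather than forced into either
state. The two thresholds are definitional defaults, exposed as
configurable parameters of `classify_state()` and of the pipeline. Mass
centers are mass-weighted over all atoms of the helix residues (whether the
original descriptive usage weighted by mass or used geometric centers is
not recoverable; mass weighting is the package's choice and is applied
consistently). Distances use raw coordinates with no periodic-image
handling: inputs are expected to be whole-molecule trajectories.

`top_top_distance()` complements this with the distance between the two
monomers' G-I mass centers, and `linear_trend()` provides the
least-squares slope/intercept/mean used to summarize drift of distance or
energy series over a time window.

# Superposition, RMSD, RMSF

`kabsch_superpose()` is the SVD form of the Kabsch algorithm with the
determinant correction that forbids reflections; it errors on collinear
selections, where the rotation is under-determined. "Backbone" and "main
chain" both mean atoms named N, CA, C, O throughout the package (the two
terms are used interchangeably in this literature and rarely defined).

`rmsf()` aligns all frames on their iteratively refined mean structure
(re-superpose, re-average, until the mean moves less than 1e-6 Angstrom)
and reports per-atom root-mean-square deviation about that mean. The
reference is the converged mean, not frame 1. Two numerical notes: the
rigid-body fit absorbs about 6/(3N) of isotropic fluctuation variance,
so tests of the sigma*sqrt(3) identity use enough atoms for that bias to be
negligible; and iid Gaussian noise of s.d. sigma per coordinate yields
RMSF = sigma*sqrt(3) only in that large-N limit.

`pairwise_rmsd_matrix()` computes all-pairs minimal RMSD fully vectorized:
nine frame-block matrix products give every pair's 3x3 cross-covariance,
and a closed-form (trigonometric) symmetric 3x3 eigendecomposition
evaluated elementwise supplies the singular values for the Kabsch formula.
A 2000-frame matrix over ~600 atoms takes seconds where a naive loop over
2 million superpositions would take hours in interpreted code; tests pin
the vectorized entries to independently computed superpositions.

# DSSP-style secondary structure

`assign_dssp()` implements the helix/turn subset of the Kabsch-Sander
algorithm. The backbone hydrogen bond is the classic electrostatic model,
`E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol with a
bond below -0.5 kcal/mol; i->i+4 bonds define 4-turns, two consecutive
4-turns make an alpha-helix (H), i->i+3 analogously gives 3-10 (G),
isolated turns are T, the rest C. Strand/bridge classes are deliberately
omitted: the target systems are all-alpha, and the analyses only track
helix stability and the turns at helix junctions. Amide hydrogens must be
present in the input; no H-rebuilding heuristic is attempted (the
synthetic generator places them). On an ideal 13-residue helix the
assignment matches a reference Kabsch-Sander implementation exactly
(H at residues 2-12), which the test suite freezes as an oracle.

# Hydrogen bonds and hydrophobic contacts

A hydrogen bond is present in a frame when the donor-acceptor distance is
at most 3.5 Angstrom **and** the D-H...A angle is at least 120 degrees;
occupancy is the percentage of frames present, reported to 0.01%. A
hydrophobic contact between two selections exists when any pair of
*nonpolar heavy* atoms (polarity class from the topology; hydrogens
excluded) is within 3.9 Angstrom -- the convention of LigPlot+-style
contact analysis; the cutoff is a parameter. Side chains, for the
minimum-side-chain-distance series, are all heavy atoms not named
N, CA, C, O. All detections are purely geometric and hence rigid-motion
invariant.

# MM-GBSA energetics

Per snapshot the package assembles, in kcal/mol:

* `G_total = H_gas + G_solvation`
* `H_gas = E_vdW + E_ele`
* `G_solvation = G_pol + G_nonpol`
* `G_nonpol = gamma * SASA + beta`, gamma = 0.005 kcal/(mol Angstrom^2),
  beta = 0

with `E_vdW` a 12-6 Lennard-Jones sum (Rmin/epsilon convention,
`Rmin_ij = rmin_half_i + rmin_half_j`, `eps_ij = sqrt(eps_i eps_j)`),
`E_ele` Coulomb with `k_e = 332.0636` kcal Angstrom/(mol e^2) and interior
dielectric 1, `G_pol` generalized Born, and SASA from deterministic
Shrake-Rupley sampling. The three composite identities hold exactly by
construction and are asserted in tests.

**GB flavor.** Effective Born radii follow the Hawkins-Cramer-Truhlar
pairwise-descreening scheme (the `igb=1` flavor of common MD codes), with
the standard 0.09 Angstrom intrinsic-radius offset, per-atom screening
factors from the topology, and solvent dielectric 78.5. An isolated atom's
effective radius equals its offset-corrected intrinsic radius; descreening
by neighbors only enlarges it. The energy is Still's pairwise expression
with `f_GB = sqrt(r^2 + a_i a_j exp(-r^2/(4 a_i a_j)))`, self terms
included. Tests check the single-ion Born closed form to machine
precision and the descreening integral against Monte-Carlo quadrature to
2%.

**SASA.** Shrake-Rupley point sampling on spheres of radius
(`lj_rmin_half` + 1.4 Angstrom probe) with a fixed Fibonacci lattice (960
points by default) replaces the analytic LCPO approximation: the point
sampling is deterministic, trivially correct in the limits the tests pin
(isolated sphere exact, disjoint additivity, full burial), and the
`gamma*SASA + beta` contract is unchanged. This is a numerical, not a
conceptual, substitution; the surface coefficient gamma is what carries
the model content.

**Binding energy.** `binding_energy()` uses the single-trajectory scheme:
`dG = G(complex) - G(monomer 1) - G(monomer 2)` with monomer geometries
cut from the complex frame. Internal bonded terms cancel identically under
this scheme, so the package never computes them, and no 1-4 scaling is
needed: gas-phase differences reduce to inter-chain LJ and Coulomb sums,
while the GB and SASA terms are recomputed per subsystem (monomer radii
are descreened only by their own chain; buried surface appears as the
per-atom SASA difference). Whole-system `frame_energy()` series
(equilibration monitoring) exclude intra-residue and adjacent-residue
pairs -- the tabular topology carries no bond list, so the 1-2/1-3
exclusion is applied at residue granularity -- and are therefore
trend-comparable across frames, not comparable to force-field absolute
energies.

**Per-residue decomposition.** Inter-chain pair energies split half to
each partner atom's residue; per-atom GB contributions are differenced
between complex and monomer; buried SASA is attributed to the atom owning
the area. Each component's residue sum reproduces the corresponding mean
binding component exactly (asserted to 1e-6 kcal/mol on a 500-frame
trajectory), and the hydrophobic part is `dE_vdW + dG_nonpol`, the
quantity whose cross-system correlation `interaction_spectrum_stats()`
reports alongside counts of residues beyond +-1 kcal/mol.

**Entropy.** Conformational entropy uses a quasi-harmonic estimator:
eigenvalues of the mass-weighted coordinate covariance define effective
oscillator frequencies `omega = sqrt(kB T / lambda)`, scored with the
quantum harmonic-oscillator entropy at the stated temperature; rigid-body
modes are removed by superposition and the residual near-zero eigenvalues
discarded. Force-field normal-mode (Hessian) entropies are out of scope,
so absolute entropy tables from Hessian-based normal-mode analysis are
not reproducible here and are not attempted; the estimator is documented
as what it is. With fewer frames than degrees of freedom the spectrum is
rank-truncated and a warning is raised.

# Clustering

`average_linkage_cluster()` wraps `stats::hclust(method = "average")` on
the pairwise RMSD matrix -- average linkage is the common default of MD
clustering tools, and the choice is deliberately conventional -- with both
stopping rules exposed: a fixed cluster count or a merge-distance cutoff.
Labels are renumbered in order of first appearance so output is
deterministic and frame-order invariant up to relabeling. The
representative structure of a cluster is the member with minimal mean
RMSD to the other members (nearest-to-center), ties to the lowest frame
index.

# The synthetic generator and what it does (not) emulate

`generate_trajectory()` builds a C2-symmetric dimer of ideal alpha-helices
(4 base + 2 hinge + 3 top per monomer by default, 8 residues each, mapped
onto segment names A-I so the helix-map machinery is exercised verbatim;
sizes shrink to `c(2, 1, 1)` for fast tests). Helix geometry uses frozen
cylindrical parameters (1.5 Angstrom rise, 100 degree twist, backbone
N/CA/C/O/H plus a CB pseudo-atom side chain) derived once from a standard
phi = -57, psi = -47 internal-coordinate construction, which yields
authentic alpha-helical hydrogen-bond geometry (i->i+4 Kabsch-Sander
energy about -2.7 kcal/mol). Per frame, each monomer's top group is
rigidly translated along its base-to-top axis so the state metric equals
`(1-theta) d_closed + theta d_open` exactly at zero noise; the schedule of
theta values is the planted conformational ground truth. Defaults
`d_closed = 33`, `d_open = 41` place both endpoints 2 Angstrom outside
the 35-37 classification band, so labels are recoverable under realistic
noise.

Noise is iid Gaussian per coordinate (default sigma 0.1 Angstrom; the
validation scenarios use 0.3). One deliberate design choice: planted
interaction-site atoms (donor/H/acceptor triples, contact carbons) are
positioned with exact bond geometry *after* noise, relative to their noisy
anchor residues. Free iid noise of 0.3 Angstrom on all three atoms would
randomly break 5-10% of genuinely "formed" bonds at the 3.5 Angstrom /
120 degree criteria -- unlike real dynamics, where a bonded hydrogen
fluctuates far less than free atoms -- making planted occupancies
systematically unrecoverable. Re-planting keeps the Bernoulli occupancy
the exact ground truth at any noise level, with recovery limited only by
binomial sampling error.

What the generator does **not** emulate: physical force-field sampling,
correlated motions, solvent, realistic side chains, or the actual 14-3-3
fold. Passing tests therefore demonstrate that the *analysis* operations
are correct against known ground truth -- not that any biological claim
about real trajectories is reproduced. Toy force-field parameters (per
element: mass, LJ, Born radius, screening factor, polarity) and charge
schemes (neutral, polar backbone, planted +-1e ion pair) exist to exercise
the energetics code, not to approximate a real force field.

# Problem sizes and numerical choices

The validation suite and the acceptance script use: 2000-frame
trajectories of the default dimer (869 atoms with one planted bond) for
state/occupancy/clustering recovery; a 500-frame small dimer (192 atoms)
for decomposition conservation, with 120 SASA points per sphere
(conservation is an exact identity at any quadrature resolution, so the
coarser lattice is used there and the default 960 where the area itself
is asserted); 1e5 sampled rotations and 50 random 8-atom instances for
the Kabsch bound; 4e5 Monte-Carlo points per pair for the descreening
quadrature. These sizes make the full suite run in about two minutes on
one core while leaving every statistical tolerance at 3 sigma or better.

Other numerical conventions: bisection recovers decision boundaries to
1e-9; the RMSF/quasi-harmonic mean-structure iteration stops at 1e-6
Angstrom; covariance eigenvalues at or below 1e-6 amu Angstrom^2 count as
unpopulated; runaway Born radii (denominator near zero under extreme
overlap) clamp at 1000 Angstrom; clustering ties inherit `hclust`'s
deterministic merge order and representatives tie to the lowest index.

# Known limitations

* No bond table: intra-chain nonbonded exclusions are residue-granular,
  so whole-system gas-phase series are trend-only. Binding energies and
  decompositions, computed from inter-chain terms and subsystem
  differences, are unaffected.
* GB is HCT-only; no OBC/GBn variants, no salt (Debye) screening, no
  Poisson-Boltzmann cross-check.
* DSSP subset omits strands, bends and pi-helices.
* The entropy estimator is quasi-harmonic, not Hessian normal-mode; use
  it for comparisons across trajectories, not absolute values.
* PDB is the only trajectory dialect (fixed-width, 1e-3 Angstrom
  precision); binary formats are out of scope.
* Donor/acceptor typing for hydrogen bonds is by explicit atom indices;
  no automatic chemistry perception.
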