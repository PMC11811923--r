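---
title: "Methods: near-attack-conformer and active-site dynamics analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: near-attack-conformer and active-site dynamics analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nacsuite)
```

## Scope and scientific setting

`nacsuite` is a post-simulation analysis toolkit for homodimeric designer
enzymes built on the LmrR scaffold, where a *para*-aminophenylalanine
(pAF) residue at position 15 performs iminium/transimination catalysis in
the hydrophobic pocket formed at the dimer interface (core residues
W96/W96′). The package covers the statistics that connect structure and
dynamics to catalytic outcome for this system:

* near-attack-conformer (NAC) extraction and pro-(R)/pro-(S) counting on
  MD trajectories, with 2-D kernel density maps of the reaction
  coordinate;
* quaternary-structure metrics on crystal structures: closest-atom
  distances between interface side chains, grid-based interface pocket
  volumes, and α1/α4 inter-helix packing angles;
* convergence and flexibility diagnostics (best-fit RMSD series, PCA
  modes, backbone RMSF);
* hydrogen-bond distance series with occupancy-based
  persistent/transient classification, arginine forward/backward
  conformer states, and cation-π geometry;
* pairwise-RMSD conformational clustering with cluster prevalences and
  representative frames;
* transition-state-theory bookkeeping of reaction-profile barriers and
  fold-rate changes.

It does **not** run simulations, docking, force-field parametrisation or
quantum chemistry: trajectories arrive as multi-model PDB files, and
reaction-profile energies are typed in by the user from their own
calculations. A seeded synthetic-data module generates every fixture the
analyses need, with ground truth returned alongside the data, so the
whole pipeline is validated by parameter recovery.

## The NAC diagnostic

For the Friedel–Crafts alkylation, the stereochemical outcome is read
from the dihedral over four atoms — the iminium carbon, the enal Cα and
Cβ, and the indole C3 — together with the distance between the two
carbons that form the new C–C bond (Cβ and C3). A frame is a pro-(S)
near-attack conformer when the dihedral lies within a window centred at
+90° and the reactive distance is below a gate; pro-(R) is the mirror
window at −90°.

The window parameters are deliberately configuration, not constants:
`nac_windows()` defaults to centres ±90°, half-width 30° and a 4.0 Å
distance gate, and every count is reported together with the windows
that produced it. The dihedral uses the IUPAC sign convention (clockwise
positive viewed along the central bond), with the atom order fixed so
that +90° maps to pro-(S); a mirror-image convention error would be
caught by the constructed-geometry tests, which build quadruples with a
known rotation about the central bond.

Density maps use an explicit product-Gaussian kernel with Silverman
bandwidths per axis. The dihedral axis is periodic, which matters when
populations sit near ±180°: kernel images at ±360° are summed before
the grid is renormalised to integrate to 1. A 15 Å truncation of the
distance axis applies to display only — counts and retention fractions
always use all frames. Record sets longer than 20,000 points are thinned
deterministically (uniform stride) before kernel evaluation; this caps
the cost at desk scale without biasing the map.

Substrate retention is summarised as the fraction of frames with
reactive distance at or below 7 Å, with a replicate counted as
"retained" when its own fraction reaches 50%. Both numbers are
configuration: the underlying observations ("barely maintained in the
pocket", "remained for five of six replicates") are qualitative, so the
package exposes the thresholds and reports them with every result.

## Structure I/O and selections

PDB v3.3 fixed-column reading and writing is implemented in the package
so the contract can be exact: one `Structure` per `MODEL`, per-line
diagnostics on malformed records, and a deterministic alternate-location
policy (highest occupancy wins; ties go to the lexicographically first
altloc) so downstream geometry always sees one conformer per atom.
Hydrogens are kept when present; every "heavy-atom" selection excludes
element H/D. Residue numbering is taken verbatim from the file (author
numbering, e.g. pAF15, R92), and insertion codes are part of residue
identity. Trajectories are multi-model PDB with a configurable frame
interval, default 10 ps — at which six 500 ns replicates contribute
exactly 3 × 10⁵ frames.

The residue name of the noncanonical pAF is not standardised across
deposited entries, so functions that need it accept it as configuration
rather than assuming a code.

## Superposition, RMSF and PCA

Superposition is the Kabsch least-squares fit via SVD of the 3×3
covariance, with the determinant correction that enforces a proper
rotation. `rmsd_series()` refits every frame on the selection before
measuring. `rmsf()` deliberately performs **no** fitting: frames are
assumed superposed (use `superpose_trajectory()`, which fits to a
reference and then refits to the mean structure — the standard two-pass
drift removal). This separation keeps the closed-form calibration exact:
pure isotropic jitter of per-axis σ gives RMSF = σ√3, whereas fitting
inside RMSF would absorb six rigid-body degrees of freedom and shrink
the value for small selections. PCA eigenvalues use the sample (n−1)
divisor so their sum equals the total coordinate variance.

## Helix axes and packing angles

A helix axis is the first principal component of the Cα trace after
smoothing with a one-turn (4-residue) moving average. The smoothing is
load-bearing: on a raw finite helix the incomplete final turn biases the
principal axis by 2–3°, while the moving average cancels the helical
radius and brings the recovery error below 0.3°. Axes are oriented N→C,
so inter-helix angles live in [0, 180°] and the convention is
unambiguous even though the LmrR packing angles of interest
(≈ 51–60°) are all below 90°.

Helix residue ranges are configuration, not auto-detected. The defaults
in `lmrr_structure_metrics()` (α1 ≈ 6–24, α4 ≈ 78–95 per chain) are
generic LmrR ranges; because the ranges actually used for published
angle measurements are not recoverable from the text, angle comparisons
against deposited structures should be read as diagnostics with a few
degrees of slack, and the ranges tuned to the entry at hand.

## Pocket volume

The interface cavity volume is a voxel computation with two probes. A
voxel belongs to the cavity when it is (a) outside every atom sphere
inflated by the solvent probe (1.4 Å), (b) flood-fill-connected to a
user-supplied seed point through such voxels, and (c) not part of the
bulk — the space a large probe (3.4 Å) can reach from the grid boundary.
If the seed's component touches bulk the volume is returned with an
`open` flag. Van der Waals radii are a fixed Bondi-style table
(C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å); spacing defaults to 0.5 Å.

Two numerical choices matter. The voxel lattice is anchored at the seed
point, not at the structure's bounding box, so the estimate does not
shift when atoms far from the cavity are added (shell-thickness
invariance is exact by construction). And the seed must sit in open
cavity space: a seed inside an atom or occluded at the probe surface is
an error, not a silent zero. For LmrR runs the natural seed is the
midpoint of the two W96 CZ2 atoms. Calibration uses hollow pseudo-atom
shells enclosing spheres of known volume: at 0.5 Å spacing the estimate
is within ~1% of 4/3 π r³ for r = 5 Å, and halving the spacing moves it
by under 2%. Agreement with published volumes from other cavity tools
should only be expected to one significant figure, since algorithms
differ in surface definition.

## Interactions

H-bonding is scored on plain donor–acceptor heavy-atom distances
(cutoff 3.5 Å, no angle term) because the analyses it supports are
distance traces; occupancy ≥ 0.5 is "persistent", (0.05, 0.5]
"transient", otherwise "absent" — all three numbers configurable and
echoed in outputs. The R92 forward/backward state uses the pAF side
chain N to guanidinium CZ distance with a 6 Å boundary (the atom pair
is standard for this system; the numeric boundary is a package default),
and the dimer state is the combination per frame: cis-forward, trans,
or cis-backward. Cation-π stacking requires the cation within 6 Å of
the ring centroid and within 30° of the ring axis; because an axial
cation cannot simultaneously present a donor in the ring plane,
`joint_occupancy()` of stacking and H-bonding on geometry-constrained
fixtures is ~0, which is the packaged mutual-exclusivity check.
Hemiaminal chirality and histidine protonation states enter only as
labels on input trajectories; no pKa or chirality computation is done.

## Clustering

`greedy_neighbor_cluster()` is the classic largest-neighbourhood
algorithm: the frame with most neighbours within the cutoff founds a
cluster, members are removed, repeat. Ties break to the lowest frame
index, making the partition deterministic; the founder is the
representative frame and prevalences are percentages of clustered
frames. The default cutoff is 1.5 Å on the user's selection (catalytic
residues, substrate atoms, or all Cα). Because the matrix is O(n²),
trajectories beyond a 5,000-frame cap must be strided; the frames used
are recorded on the matrix and in the cluster result.

## Energetics

Profiles are ordered stationary points alternating minimum / transition
state. Two barrier conventions are exposed: `"step"` (TS minus the
immediately preceding minimum) and `"span"` (TS minus the lowest
preceding minimum), with span the default because overall barriers for
multi-step sequences are conventionally quoted against the lowest-energy
preceding conformer. Rate conversions use
k₂/k₁ = exp(ΔΔG‡ / RT) with R = 1.987204 × 10⁻³ kcal mol⁻¹ K⁻¹ and a
default temperature of 298.15 K, exposed as an argument since reported
fold-changes rarely state the temperature behind them.

The shipped `energy_profiles_example.tsv` encodes (S)- and
(R)-configured hemiaminal pathways whose step and span barriers equal
the published values for this system (15.2 and 8.7 kcal/mol on the (S)
path; 11.0 and 19.4 on the (R) path). Only barriers are printed in the
source text, so the intermediate minima in the table are illustrative
choices constrained to reproduce every quoted step and span barrier
simultaneously; all barrier arithmetic is invariant to the remaining
freedom.

## The synthetic-data generators

Every generator is a pure function of its configuration, including the
seed, and returns its own ground truth:

* `make_nac_trajectory()` samples a mixture over (dihedral, distance) —
  wrapped-normal angles (or uniform for the unreactive background),
  zero-truncated normal distances — and *constructs* six fragment atoms
  so the measured values equal the sampled ones exactly: three atoms are
  fixed and the indole carbon is placed by azimuthal rotation about the
  Cα→Cβ axis, with the azimuth equal to the target dihedral. Defaults
  mirror the study conditions: 6 replicates × 50,000 frames at 10 ps
  (3 × 10⁵ frames), a 95% broad background and a 5% pro-(S) component.
  Wrapped-normal sampling is adequate for σ ≤ 60°; the background uses
  an exact uniform instead.
* `make_hbond_series()` is a two-state Markov dwell process with
  geometric dwell lengths (default mean bound dwell 5 frames — tens of
  ps, typical of transient H-bonds at this frame spacing); the unbound
  dwell is set from the target stationary occupancy, and the realised
  occupancy is returned.
* `make_two_state_trajectory()` draws frames from jittered reference
  conformers in stated proportions (default 70/30, jitter 0.05 Å,
  conformer separation ≳ 2 Å RMSD) for clustering recovery.
* `make_ideal_helix()` / `make_helix_pair()` build standard α-helix
  Cα geometry (rise 1.5 Å, twist 100°, radius 2.3 Å) at controlled
  inter-axis angles; `make_hollow_shell()` tiles Fibonacci-lattice
  spheres of carbon-like pseudo-atoms whose innermost layer is placed so
  the probe-excluded cavity is an analytic ball.

What the generators emulate is the *statistical* structure the analyses
assume — mixture populations on the reaction coordinate, dwell
processes, well-separated conformers, ideal secondary structure. What
they do not emulate: force-field energetics, correlated protein motion,
solvent, anharmonicity, or the coupling between pocket geometry and
substrate dynamics. Passing recovery tests therefore demonstrates that
the estimators are correct and calibrated, not that any particular
biological conclusion holds on real trajectories.

## Numerical choices and degenerate inputs

* Dihedrals are undefined for collinear/coincident consecutive points
  and raise an error rather than returning 0.
* Kabsch superposition raises a rank error on collinear point sets;
  the returned rotation always has determinant +1.
* `min_pairwise_distance()` resolves ties to the lowest index pair;
  clustering ties break to the lowest frame index; altloc ties to the
  first altloc code — every tie-break is deterministic.
* KDE on zero-spread records is an error suggesting a bandwidth floor,
  never a silent delta function.
* Angle wrapping maps to (−180°, 180°]; window-overlap checks use the
  wrapped difference of the two centres.
* Generators restore the caller's RNG state, so library use never
  perturbs a user's random stream.

## Problem sizes used in the shipped tests

The test suite and the acceptance script regenerate everything they
measure. Sizes were chosen as the smallest that make the statistical
assertions sharp: 10⁵ random quadruples for the dihedral oracle, 10⁵
frames for RMSF and NAC-fraction recovery (3 binomial SE), 10⁴ frames
for H-bond occupancy (±0.02), 10³ frames for clustering prevalences
(±2 points) with brute-force equivalence checked exhaustively at 50
frames, and the full 3 × 10⁵-frame accounting run once. The
deposited-entry metrics (`lmrr_structure_metrics()`) run only when the
user supplies the corresponding PDB files, which the package cannot
redistribute.

## Known limitations

* The H-bond criterion has no angular term; on real trajectories this
  overcounts marginally bent contacts near the cutoff.
* The helix axis is a principal component, not a rotational fit; for
  strongly curved helices the packing angle can deviate a few degrees
  from helix-fitting methods, and published angles may have used
  different residue ranges.
* The pocket estimator is grid-based with voxel-centre counting;
  sub-voxel surface detail is lost, and cross-tool volume agreement is
  one-significant-figure territory.
* Clustering above the frame cap relies on uniform striding; rare
  states thinner than the stride can be missed.
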