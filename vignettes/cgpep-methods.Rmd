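---
title: "Coarse-grained screening of short peptide self-assembly with cgpep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained screening of short peptide self-assembly with cgpep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Short peptides (one to three residues) such as diphenylalanine (FF)
self-assemble in water into supramolecular structures - tubes, vesicles,
bilayers, fibres - and coarse-grained (CG) molecular dynamics with
MARTINI-style force fields is the standard computational route to predicting
which sequences assemble and into what.  The successive generations of these
force fields, however, balance hydrophobicity differently: the 2.1-generation
parameters make FF aggregate readily and form its characteristic tubes, the
2.2 generation (more hydrophilic aromatic beads) leaves FF in solution, and
the third generation - despite its richer bead-size palette - also fails to
aggregate FF unless the aromatic side-chain and charged-terminus beads are
reassigned.  `cgpep` packages the complete desk-scale methodology for
studying this: the bead tables and interaction matrices of the three
generations, a topology builder, a minimal NPT engine with the exact
interaction settings used in this field, the quantitative screening metrics
(aggregation propensity, side-chain RDF, group temperatures, morphology,
tube fractions), and a screening orchestrator.

## The model

**Beads and interactions.** Each residue maps to one backbone bead plus 0-4
side-chain beads.  Bead sizes are regular (sigma 0.47 nm), small (0.43 nm in
the v2 generation, 0.41 nm in v3) and, in v3 only, tiny (0.34 nm); an F side
chain is one small bead (the C-beta plus two ring carbons) and two beads for
the remaining ring carbons - small in v2, tiny in v3.  Nonbonded
interactions are Lennard-Jones with a pair-specific epsilon from the
generation's interaction matrix, cut off at 1.1 nm with a potential shift,
plus reaction-field electrostatics (dielectric constant 15 inside the
cutoff, conducting boundary beyond it) between the charged beads: the
protonated N-terminus (+1), deprotonated C-terminus (-1), lysine side chain
(+1), aspartate (-1), and counter-ions.

The published record of these matrices is partial.  Every entry the
interaction analysis prints (for example SC4-SC4 dropping from 3.5 to
2.35 kJ/mol between generations, SC4-water from 2.7 to 1.80, Q5-water 5.64)
is stored verbatim and tagged `paper-printed`; a handful of values carried
from the public distributions (water-water 4.65 kJ/mol, the size-class
sigmas, bead masses) are tagged `transcribed`; all remaining entries are
reconstructed from the documented level structure of the force field -
monotone hydrophobicity series within a bead row, geometric interpolation
across rows - and tagged `approximated`.  `interaction_matrix()` exposes the
tags so users can audit which numbers are load-bearing, and
`read_itp_nonbonded()`/`override_interactions()` let a user substitute a
full distributed table.  One transcription convention deserves note: the
v2-generation distributions run ring-ring (S-S) pairs at 75% of the
tabulated level epsilon with sigma 0.43.  The stored tables keep the printed
level values (so lookups reproduce the published numbers exactly); the
engine applies the 75% ring convention through a separate `eps_engine`
table, which restores the distributed force field's physics.

**Parameter sets.** `make_parameter_set()` resolves the named sets - the
v2.1 coil/extended pair (differing only in the backbone bond force constant,
400 vs 1250 kJ/mol/nm^2), v2.2 (ring SC5, bonded terms equal to v2.1
extended), v3 (ring SC4/TC5, termini Q5) and v3opt (ring SC4/SC4, termini
Q4, with the W and Y aromatic hydrophobic beads also moved to SC4) - and
grid codes of the form `"SC3/TC3-Q3"` (first ring bead / outer ring beads -
terminus bead).  `screening_grid()`/`enumerate_grid()` span the standard
screen: S-only, T-only, S/T-combined and h-variant rings over C2-C5 by
termini Q1-Q5 (80 sets).  The `h` ("higher self-interaction") beads are
implemented as the base bead with h-h pair epsilons scaled by a configurable
factor (default +10%); the literature states the intent of these beads but
not the increment, so the factor is an explicit, documented choice.

**Topology.** Aromatic rings are rigid bodies: every intra-ring bead pair is
constrained at its template distance (two 3-bead rings give FF its 6
constraints), maintained by an iterative SHAKE-style solver to a relative
tolerance of 1e-4 per step.  The backbone-backbone bond force constants are
the published 400/1250; other bond lengths (0.31-0.35 nm), the 0.27 nm ring
edges (0.30 nm for mixed-size edges) and the side-chain/backbone angles are
carried from the public releases and are not claimed beyond that provenance.

**Engine.** Leapfrog integration at 25 fs; neighbour list (cell list plus
0.2 nm Verlet skin) rebuilt every 10 steps; stochastic velocity-rescale
thermostat (303 K, tau 1 ps) with centre-of-mass motion removal; isotropic
Berendsen barostat (1 bar, tau 3 ps, compressibility 3e-4 1/bar - the
standard CG value, chosen here as the sources leave it unstated); steepest
descent minimization until the maximum force falls below 2000 pN or 5000
steps.  Forces are the exact negative gradient of the shifted potential
(finite-difference validated to a relative error below 1e-4), NVE
fitted-slope energy drift at reduced time step stays below 1e-3 of the mean
potential energy on a moderate-well LJ liquid, and runs are
deterministic under a fixed seed (one self-contained xoshiro256+ stream
drives velocity generation and the thermostat).  The Berendsen virial omits
the constraint contribution; this biases instantaneous pressure slightly but
only shifts the equilibrated density imperceptibly at these system sizes.
Reported "effective" times multiply simulated time by the conventional
factor 4 for CG dynamics (50,000,000 steps x 25 fs x 4 = 5 microseconds).

**System assembly.** Molecules are inserted as random rigid bodies with a
0.21 nm minimum-image clearance (GROMACS-like); water beads (one per four
real waters) fill the remaining space at the reference density of
8.3 beads/nm^3, leaving a 0.4 nm clearance shell that the barostat closes
during equilibration; counter-ions replace water beads until the net charge
is zero (zwitterionic FF needs none).  Antifreeze particles are omitted -
simulations run at 303 K in small boxes where freezing artefacts do not
arise - a documented deviation from some CG workflows.  Concentrations are
computed exactly as N/(N_A V); the published tables round differently in
places (e.g. 300 molecules in a 12.5 nm box is 255 mM here, printed as 256,
and 800 in 17.0 nm is 270 mM, printed as 267), and the package reports the
exact value rather than matching the rounding.

## The metrics

* **Aggregation propensity (AP)** - the ratio of solvent-accessible surface
  area (SASA) between the first and last frame of a run, reported to one
  decimal; AP >= 2 is read as aggregation.  SASA uses Shrake-Rupley with a
  deterministic golden-spiral point set (960 points/bead), a 0.14 nm probe,
  and bead radii of half the self-interaction sigma.  The radii convention
  of the original analysis tool is version-dependent and unpublished, so
  absolute SASA (hence AP at intermediate aggregation) can shift with the
  radii choice; AP orderings across parameter sets are the robust contract,
  and the radii are configurable.
* **Side-chain RDF** - g(r) of the mass-weighted aromatic side-chain centres
  of mass, 0.01 nm bins, normalized against the ideal gas under periodic
  boundaries, computed over the last 20% of frames (the desk-scale analogue
  of analysing the final microsecond); its global maximum locates the
  pi-stacking distance.
* **Group temperature** - kinetic temperature of groups of solute molecules
  with degrees of freedom reduced by the constraints each molecule carries
  (3N/(3N - c); 24/18 = 1.333 for FF), the standard check that constrained
  solutes are not thermostatted to a different temperature than the solvent.
* **Morphology** - the published screens assessed shape visually; here the
  call is algorithmic: single-linkage molecule clustering at a 0.6 nm bead
  cutoff (largest-cluster mass fraction below 0.5 is "solution"), a 0.5 nm
  voxelization with outside flood-fill for enclosed interior voids
  ("vesicle" at >= 5% void), a projected through-channel test along each
  gyration principal axis ("tube" when an enclosed cross-section of at
  least ~1 nm^2 survives projection), gyration-tensor flatness for
  "bilayer", percolation across >= 2 box axes for "spanning_artifact"
  (excessive binding across the periodic boundaries), and "solid"
  otherwise.  Occupancy is dilated by 1.5 voxels so that statistical pores
  in walls of realistic bead density do not leak the flood fill; these
  thresholds are validated against the labelled synthetic fixtures
  (`generate_fixture()`) only and are not claimed to reproduce the
  published visual calls on the original trajectories.
* **Tube fraction** - the fraction of replicas whose final label is "tube",
  with SEM = sd/sqrt(n - 1), and phase tables with majority votes per grid
  cell (ties break toward the less-ordered class, conservative against
  false tube claims).

## Desk-scale study conditions

The published screens used 300-1600 molecules for 5 microseconds of
effective time; that is cluster-scale.  The package supports those protocols
but its test suite and examples run a scaled-down preset chosen once:

* *Non-aggregation check*: 50 FF molecules in an 8.5 nm box (135 mM, the
  concentration of the original assessment) under the v3 set - the
  dispersed state is stable, so moderate run lengths (>= 1e5 steps,
  2.5 ns simulated / 10 ns effective) suffice to read AP = 1.0.
* *Version ordering*: 16 FF molecules in a 4.65 nm box (264 mM - the
  screening window of ~256-267 mM that was chosen in the original protocol
  precisely to speed up self-assembly), 1e5 steps (2.5 ns simulated, 10 ns
  effective), four seeds per parameter set.  At this scale the aggregating
  sets (v2.1-E, v3opt) bury surface within the run while v2.2 and v3 stay
  dispersed.  Mean APs are compared after rounding to one decimal, the
  reporting convention of the field.  One caveat is intrinsic to desk
  scale: for two sets that both stay in solution (v2.2 and v3, full-scale
  APs 1.2 and 1.0) the expected difference is smaller than the AP noise of
  a 16-molecule system, where a single transient dimer in the final frame
  moves AP by roughly 0.15; their desk-scale ordering is therefore not
  resolvable and the corresponding check documents this rather than
  claiming it.
* *Stacking distance*: an aggregating S-only set (SC3/SC3-Q3) at the same
  scale, with the RDF computed over the last 20% of frames.  The 0.5-0.6 nm
  stacking band is resolved, but with a few dozen aromatic centres the
  global maximum hops among contact-geometry sub-peaks and tends to sit at
  the face-to-face contact distance (~0.51 nm) rather than at the 0.60 nm
  offset-stacking value seen at full scale; the corresponding check
  documents this bias rather than hiding it (the rings carry no
  orientation-restraining terms beyond one backbone-ring angle, which
  favours compact face-to-face stacking).

What the scaled-down conditions do show: the relative hydrophobicity
rankings of the parameter sets, the non-aggregation of v3, the recovery of
aggregation under v3opt, and the S-bead stacking distance.  What they do not
show: actual tube formation (the published screens found tubes only with
hundreds of molecules in >= 17 nm boxes), concentration-dependent tube
fractions, or any quantitative AP at full scale; the morphology classifier
is therefore validated on synthetic geometries rather than on desk-scale
trajectories.

## Numerical choices and degenerate inputs

Tolerances: SHAKE relative tolerance 1e-4 (500 iteration cap); minimizer
step adaptation 1.2x/0.2x with a 0.01 nm initial displacement; neighbour
search falls back to brute force when the box holds fewer than three cells
per edge.  Barostat scaling per step is clamped to [0.98, 1.02] to keep the
early post-solvation equilibration stable.  Degenerate inputs fail loudly:
unknown beads name the bead and version, malformed grid codes echo the
offending token, insertion reports the achieved count, zero final SASA and
empty frames are errors, and a single replica has no defined tube-fraction
SEM.  Single-residue peptides place both termini charges on one bead and
are modelled as a neutral zwitterionic bead.

## Design decisions that were genuinely open

* S3 classes and plain functions (in the style of desk-scale structural
  tools) rather than S4 containers: the central objects are bead tables,
  parameter sets and trajectories, none of which map onto the established
  genomic data structures.
* The reaction field uses a conducting boundary (eps_rf -> infinity), the
  common CG practice where only the inner dielectric (15) is stated.
* The constraint solver is SHAKE-style with a stated tolerance rather than
  an emulation of LINCS order 4; the contract is "constraints satisfied to
  tolerance each step", not algorithm identity.
* The modern Verlet potential-shift convention is used for Lennard-Jones
  (older v2-era workflows sometimes used a force switch); the difference is
  a smooth constant offset that cancels in AP and RDF.
* The `h`-bead increment (+10% on h-h pairs) and the approximated matrix
  entries are single, documented choices made before any simulation-based
  test was run, and are not tuned.

## Known limitations

Pure-R/C++ desk-scale engine: no PME, no domain decomposition, isotropic
pressure only, cubic boxes only, peptides of at most three residues.  The
approximated matrix entries reproduce the level *structure* of the force
field, not its exact published tables; conclusions should rest on the
paper-printed anchors and on orderings, which is how the test suite uses
them.  Morphology classification at desk scale labels small aggregates
(typically "solid" or "solution"); tube formation itself requires
cluster-scale runs that the package supports but does not test.
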