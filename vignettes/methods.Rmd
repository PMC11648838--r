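---
title: "Methods: flat-histogram sampling, backmapping and energy calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flat-histogram sampling, backmapping and energy calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`prime20samc` implements a four-bead coarse-grained peptide representation:
each residue carries three backbone beads (amide NH, C-alpha, carbonyl CO)
and one sidechain bead at the sidechain centre of mass. Chains live in a
periodic cubic box (default edge L = 150 Angstrom, matching a millimolar
polyglutamine dimer); coordinates are stored wrapped into [0, L) and all pair
distances use the minimum-image convention.

The Hamiltonian has two ingredients:

* **Constraints.** Pseudo-bonds (NH-CA, CA-CO, CO-NH', CA-SC, plus the
  angle-fixing NH-CO and CA-CA' pseudo-bonds) must stay within a fractional
  tolerance (default 2.375%) of their reference lengths, and non-bonded
  beads may not overlap their hard-sphere contact distance. A configuration
  violating any of these is simply not a state of the model.
* **Square-well attraction.** An NH...CO pair whose distance falls inside
  the backbone well counts as one hydrogen bond; SC-SC and SC-backbone
  pairs inside their wells count as sidechain interactions. The dimensionless
  energy is `E = -w_bb * N_backbone - w_sc * N_sidechain` with weights 1.0
  and 0.08.

Counting details the model itself does not fix, and the package's choices:

* **Saturation.** Each NH donor and each CO acceptor joins at most one
  hydrogen bond; when several candidates fall inside the well they are
  matched greedily by ascending distance with deterministic index-order tie
  breaks (physical saturation; determinism for testing). Sidechain
  interactions are matched the same way, independently.
* **Locality.** Intra-chain pairs closer than 3 residues are not counted
  (standard practice in coarse-grained peptide models); intra-chain pairs up
  to 1 residue apart are exempt from the excluded-volume check because the
  pseudo-bond network already fixes their geometry.
* The well criterion is distance-only; no orientation term (none is defined
  for the model).

The numeric parameter values (bead diameters 3.3 / 3.7 / 4.0 / 4.5 Angstrom,
bond lengths 1.46 / 1.51 / 1.33 Angstrom, well bounds) follow the published
PRIME/PRIME20 parameterization where available and are otherwise
representative choices for glutamine. They are *defaults*, not assumptions:
every value can be overridden through `p20_params()` or a JSON parameter
file, and the test suite parameterizes over them. The sidechain weight is
0.08 per the energy expression; note the model literature elsewhere quotes
1/12 (= 0.0833...) per sidechain interaction -- the discrepancy is recorded,
not resolved, and `w_sc` is configurable.

## Density-of-states estimation (SAMC)

Stochastic-approximation Monte Carlo estimates log g(U) so that sampling
with acceptance probability `min(1, g(current)/g(proposed))` visits all
energy levels evenly. After every step (accepted or not) the log-DOS of the
post-decision level is incremented by `gamma_t = min(gamma0, t0/t)`; the run
stops at the first step with `gamma_t < gamma_min` (default 1e-7).

Design choices where the algorithm statement leaves freedom:

* The DOS update is performed in the **log domain** (`log g += gamma_t`),
  the standard convergent form; the DOS spans too many orders of magnitude
  for a linear update.
* Levels are keyed by the **exact integer pair** `(N_backbone,
  N_sidechain)`, not by floating-point energy bins: the energy lives on an
  exact lattice, so binning would only introduce ambiguity, and distinct
  count pairs remain distinct even if their energies collide numerically.
* Newly encountered levels are lazily initialized to the current minimum
  log-DOS, which encourages exploration of fresh levels.
* Constraint-violating proposals are treated as rejected moves and trigger
  the same rejection-branch update, keeping the update rule total.
* The four move types (single-bead displacement capped at 0.02 Angstrom,
  Phi/Psi pivot, whole-chain rotation, whole-chain translation) default to a
  uniform mix; pivot and chain moves are rigid, so they preserve pseudo-bond
  lengths exactly, while displacements explore the bond-tolerance band. The
  pivot rotates the C-terminal arm (for a Phi axis the residue's own CO and
  SC rotate too; for a Psi axis rotation starts at the next residue). Pivot
  angle and chain-move magnitudes have no canonical literature values; they
  default to pi, 1 Angstrom and pi and are configurable.
* Production runs hold the DOS fixed (read-only) and collect snapshots into
  per-level reservoirs: the first visit to a level is always recorded, then
  every `snapshot_stride` steps with reservoir downsampling to
  `level_quota`, so every visited `(N_backbone, N_sidechain)` pair is
  represented -- the stratification the downstream calibration needs.

### What the toy tests establish (and what they do not)

The headline correctness property -- converged log-DOS differences match an
independent reference within 0.2 -- is checked on a deliberately small
stated world: two 2-residue glutamine chains in a 14-Angstrom box,
restricted to rigid whole-chain moves. Restricting to rigid moves makes the
configuration space a product of rigid-body poses, so the exact DOS can be
computed by brute force: drop both chains uniformly at random (uniform
positions, Haar-random orientations), reject invalid placements, and tally
levels; level counts are then proportional to g. Two parameter variants
(backbone-only wells and sidechain-only wells, the disabled channel's well
placed below hard-sphere contact) keep the level space to ~5 levels each, so
a run of at most 1e6 steps (schedule `gamma0 = 1, t0 = 30, gamma_min =
3e-5`) genuinely converges; with 18+ levels and both channels active the
logarithmically-decaying schedule would need orders of magnitude more steps,
which is precisely why the full-scale runs in production use ~1e9 steps.
The toy run's statistical scale was chosen a priori by this reasoning, not
tuned to the tolerance.

A green toy test establishes that the sampler's acceptance rule, update
rule, bookkeeping and move generation are correct. It does *not* establish
convergence-rate adequacy for the 26-residue dimer, and the visitation
flatness of a 1e6-step toy run is seed-sensitive when a very rare level is
discovered late (rare-level dwell times under flat-histogram dynamics are
long). One caveat worth recording: the early brute-force oracle fixed the
first chain's orientation and disagreed with the sampler by a systematic
~0.15; the minimum-image fold of a periodic box is not rotation-invariant,
so the oracle must randomize both chains. The shipped oracle does.

Two exactness notes. The bookkeeping identity "sum of all log-DOS increments
equals the summed schedule" is asserted to 1e-9 relative rather than
bit-exactly: both sides sum the same multiset of doubles in different
association orders. And `gamma_min = 1e-7` termination is exercised with a
deliberately tiny `t0` (the threshold crossing is at `t = t0/gamma_min`
steps, so the literature-scale `t0` would require ~1e11 steps).

## Backmapping

Backbone N, CA and C atoms are taken verbatim from the beads. The carbonyl
oxygen of peptide bond i is placed in the plane of (CA_i, C_i, N_i+1) along
the bisector of the two C-centred bonds at C=O = 1.23 Angstrom, and the
amide proton is constructed *in the same plane*, anti to the oxygen across
the C-N axis (C-N-H angle 119 degrees, N-H 1.01 Angstrom) -- this makes the
coplanarity determinant and the 180-degree O-C-N-H dihedral exact by
construction, which is what the geometry tests assert. Termini are built
charged: three tetrahedral ammonium protons (reference torsion 180 degrees
from the C-CA-N plane) and a symmetric carboxylate pair (O-C-OXT 126
degrees, C-O 1.25 Angstrom).

Each sidechain is a rigid equilibrium-conformation template (glutamine:
ideal bond lengths/angles, chi angles all-trans). The rigid placement is
exactly determined up to one torsion: the mass-weighted sidechain COM is
pinned to the CG bead and the template's internal CA-to-COM axis is aligned
with the snapshot's CA-to-bead direction. The free torsion about that axis
is resolved by sampling K = 36 rotations and keeping the one with the
fewest steric clashes against atoms of previously placed residues
(deterministic tie-break on the torsion index). The alpha hydrogen is added
tetrahedrally from N, C and CB. Where the COM/axis placement and an ideal
tetrahedral CB direction conflict, COM alignment wins and CB sits where the
rigid transform puts it.

Wrapped snapshots: atoms follow each residue's stored (wrapped) bead
positions (derived atoms may poke slightly outside the box). Backbone atoms
are pinned to the stored bead coordinates bit-exactly, which is what makes
the CG round-trip test an identity on the backbone; sidechain COMs
round-trip to < 1e-6 Angstrom (floating-point rigid-transform error only).

Clash detection reports every atom pair more than two covalent bonds apart
that is closer than 0.6 (configurable) times the sum of Bondi van der Waals
radii. Clashes are *reported, not repaired*: geometry relaxation belongs to
the downstream MD tooling, and close contacts between adjacent residues are
expected in raw backmapped structures before minimization.

## Calibration statistics

The statistics layer assigns kJ/mol per model unit by ordinary least
squares of averaged atomistic energies against model energies. Choices:

* **Effective sample count.** MD total-energy samples are strongly
  correlated, so `N = floor(T / tau)` with `tau` a typical hydrogen-bond
  network relaxation time (default 10 ps), and `SEM = sd / sqrt(N)`. This
  is deliberately the simple lifetime heuristic, not a block-averaging or
  autocorrelation-integrated estimator; for an AR(1) process the heuristic
  is accurate to a factor `sqrt((1+phi)/(1-phi) * tau/dt... )` of order
  one, and the test asserts the documented factor-2 envelope rather than
  equality. `sd` is always computed from the trace itself.
* **OLS is unweighted by default** (plain regression); 1/SEM^2 weighting is
  available behind a flag.
* **Running averages** use a truncated centered box window.
* **Half-split check** draws floor(n/2) samples uniformly without
  replacement; for iid noise the RMS full-vs-half difference has the closed
  form `sigma * sqrt(1/floor(n/2) - 1/n)`, which the replicate test uses as
  its oracle.
* **Synthetic traces** are AR(1): the simplest process with a defined
  correlation time -- exactly what the `N = T/tau` heuristic presumes. The
  generator's defaults mirror the published analysis scale: 10 ns traces,
  sigma = 620 kJ/mol, tau = 10 ps, giving N = 1000 and SEM ~ 19.6 kJ/mol
  (6.2 kJ/mol for tau = 1 ps). The reference energies (-215346 kJ/mol for
  the water box, -5392 kJ/mol per peptide, -226130 kJ/mol combined) are
  consumed as inputs, never recomputed: no MD engine is in scope. Where an
  externally quoted one-sigma interval disagrees with the trace's own
  standard deviation, the package always sides with the computed per-trace
  sd.
* **Sidechain series power.** The "zero sidechain slope, |slope| < 1
  kJ/mol" replicate check needs the slope standard error to be well below
  1: with sigma = 20 kJ/mol noise and sidechain counts spanning 0..40
  (x-spread 3.2 model units), 2000 points per group give SE ~ 0.47, so
  ~96% of replicates land inside +/-1. The group size was fixed by this
  power calculation before the test was run; at a realistic ~10 MD-averaged
  points per group the bound would not be statistically resolvable, which
  is why the sidechain conversion factor is best reported as practically
  zero rather than as a measured value.

The AR(1) stand-in reproduces the marginal variance and correlation time of
an MD energy trace but none of its slow conformational drifts,
multi-timescale relaxation or anharmonicity; a green statistics test
validates the estimators, not the physics of any particular MD run.

## Degenerate inputs and numerical conventions

Minimum-image components lie in [-L/2, L/2); wrapped coordinates in [0, L).
Square-well bounds are inclusive on both ends. Collinear backbone triplets
abort backbone completion with the residue named; a zero-length CA-to-COM
vector aborts sidechain placement. The system builder retries randomized
placements (jitter amplitude growing with the attempt) and reports the
first violated constraint if the budget is exhausted; a box smaller than
the extended chain plus one contact distance is rejected outright.
Per-stage seeds are derived from one global seed by hashing the stage name
(FNV-1a), so every pipeline stage is independently reproducible and reruns
are byte-identical.

## Known limitations

* Only a glutamine template and glutamine-fidelity parameters ship;
  the framework is sequence-generic but other residues need their own
  template and parameter entries.
* No solvent beads, no electrostatics, no temperature-dependent potential
  at the CG level; no energy minimization or rotamer search at the
  all-atom level.
* The sampler's convergence diagnostics (flatness, oracle comparison) are
  toy-scale instruments; production-scale runs should monitor the
  visitation histogram directly.
* `interaction_delta` is exact but recount-based: the saturation matching
  is a global assignment, so a purely local incremental update would be
  incorrect; on systems of this size the recount is not the bottleneck.
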