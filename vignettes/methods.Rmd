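---
title: "Event-driven replica-exchange dynamics for helical propensity profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-driven replica-exchange dynamics for helical propensity profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rexdmd)
```

## The problem

Intrinsically disordered proteins (IDPs) lack a stable fold, but many carry
short *pre-structured motifs* (PreSMos): stretches of sequence that
transiently populate alpha-helical structure in the unbound state and often
coincide with the elements seen folded in complexes. `rexdmd` implements a
complete desk-scale pipeline for detecting such motifs by simulation:
event-driven (discrete) molecular dynamics of a coarse-grained peptide
model, temperature replica exchange for sampling, and the ensemble analysis
that turns conformations into per-residue helical propensity profiles,
continuous-helix maps, Ramachandran occupancies, density-of-states surfaces
and called PreSMo intervals matched against reference annotations.

All units are reduced: the Boltzmann constant is 1, temperature and energy
share one scale, and times are "time units" (tu). No physical calibration of
these scales is attempted.

## The chain model

Each residue contributes four beads — backbone N, CA, C and a side-chain CB
(glycine has none) — of unit mass. Covalent bonds and bond angles are
infinite square wells ("distance windows") centred on canonical peptide
geometry: bonds N-CA 1.46, CA-C 1.53, C-N 1.33, CA-CB 1.53 A with ±2%
half-width; 1-3 pseudo-bonds fixing the backbone and CB angles, plus a
CA(i)-CA(i+1) pseudo-bond that keeps the peptide bond trans, all with ±5%
half-width. Within these windows the only remaining soft degrees of freedom
are the phi/psi torsions — exactly what the downstream analysis consumes.
Termini are left uncapped. L-chirality is fixed by the CB improper torsion
(C, N, CA, CB) = -120 degrees, matching the standard IUPAC dihedral sign
convention (verified against independent structural libraries in the test
suite).

## The stepwise force field

Nonbonded pairs interact through piecewise-constant radial potentials:

* a hard core per bead-kind pair. Core diameters were derived by dense
  sampling of the sterically legitimate torsion basins (the left half-plane
  of the Ramachandran map for CB-bearing residues) and set to 95% of the
  closest approach observed, so no legitimate backbone motion is blocked
  while self-intersection is excluded. Pairs within one residue of each
  other use cores scaled by 0.88 for the same reason.
* a single shallow attractive shell (depth 0.05, width 1 A) for nonlocal
  pairs — the minimal stepwise discretisation of dispersion/solvation
  attraction — and an optional CB-CB hydrophobic well with per-residue
  scale, off by default.

### Helix-stabilising hydrogen-bond rules

The model's central feature is a sequence-dependent i to i+4 backbone
hydrogen-bond proxy: a square well between C(i) and N(i+4) of depth
`hb_eps * w(aa_i) * w(aa_i+4)`, where the bundled weight table `w`
(normalised to w(Ala) = 1) follows the experimental helix-propensity
ordering of the amino acids, so alanine-rich stretches helicise most readily
and glycine/proline interrupt.

A real backbone hydrogen bond is angular as well as radial. In a stepwise
model the standard trick is to gate the well on auxiliary distances, and the
gating here is deliberately strict — the well counts only while *all* of the
following windows hold:

* the contact window C(i)-N(i+4) in (3.95, 4.65) A;
* a span gate CA(i)-CA(i+4) in (5.9, 6.95) A;
* per-torsion gates pinning the six bridged torsions phi/psi(i+1..i+3):
  d(C(m-1), C(m)) is a monotone function of cos(phi_m) and d(N(m), N(m+1))
  of cos(psi_m), so a distance window is exactly a torsion-magnitude
  window;
* chiral gates. All backbone 1-4 distances are mirror-even, so the windows
  above would accept the left-handed mirror helix equally well. Distances
  involving CB are not: d(C(m-1), CB(m)) and d(CB(m), N(m+1)) single out the
  torsion sign, and a CB(i)-CA(i+3) span gate (6.0, 7.1 A; the mirror helix
  sits at 4.6 A) discriminates the handedness of the whole turn. The
  intersection of the even and chiral windows is exactly the right-handed
  alpha basin. Chiral gate windows carry a 0.15 A slack absorbing the
  smearing of the distance-torsion map caused by the finite bond windows;
  the mirror basin remains excluded by a large margin (asserted by a unit
  test). Glycine, having no CB, falls back to achiral gates.

The rule state is purely geometric and can only change at a boundary event
of one of its member pairs, where the energy step is applied to the crossing
pair — so the multi-body interaction conserves energy exactly, event by
event.

Finally, each torsion-gate window carries a small unconditional square well
(0.7 inside the even windows, 0.5 inside the chiral ones) and the contact
window one of 0.3. These act as a helical dihedral bias: individual residues
are paid for visiting the helical basin *before* a full turn assembles,
which is what makes spontaneous nucleation kinetically accessible at
desk-scale run lengths. Without a gradient, assembling a first turn would
require a simultaneous ~15-window coincidence and essentially never happens.

With `hb_eps = 3.5` (the shipped default) a 16-residue polyalanine folds
from the fully extended state within a few thousand tu at the coldest rung
of the default ladder and is molten at the hottest — the melting transition
falls inside the ladder, which is the regime the method needs. This
calibration was fixed once, before the acceptance suite was finalised, and
is shipped as `inst/extdata/forcefield_default.txt` (every value
overridable; the compiled force field logs the file's checksum for
provenance).

## The event engine

Between events every bead flies ballistically. Events are:

* **pair events** — the earliest positive root of |r + v t| = R over all
  reachable shell boundaries, resolved with exact momentum and energy
  conservation: a crossing is allowed iff the radial kinetic energy
  0.5 mu vr^2 exceeds the energy step, else the pair reflects elastically
  (vr to -vr); tangential components never change;
* **ghost collisions** — the Andersen-style thermostat redraws one uniformly
  chosen bead's velocity from the Maxwell-Boltzmann distribution at T, as a
  Poisson process with rate HEX x n_beads. HEX = 0 gives strictly
  microcanonical dynamics (energy drift below 1e-8 over tens of thousands of
  events is asserted in the tests; observed drift is ~1e-12);
* frame saves and neighbour-list rebuilds.

Numerical choices: boundary coincidence tolerance 1e-9 A with a relative
nudge of 1e-9 to the post-event side of the boundary to avoid re-collision
loops; lazy queue invalidation via per-bead collision counters; one
deterministic RNG stream per engine call (Mersenne Twister with an explicit
Box-Muller transform, so trajectories are bit-reproducible across
platforms); a Verlet neighbour list with 0.8 A skin whose rebuild interval
skin/(2 v_max) guarantees no unlisted pair can come into range, with an
immediate rebuild whenever any speed exceeds the v_max used to schedule it.
Because two events on a shared bead can coincide in time, a pair sitting
exactly on a wall can be nudged marginally to the illegal side; the engine
detects this and schedules an immediate recovery event, and walls pass
crossings *towards* the legal side freely, so such excursions are healed at
machine precision rather than accumulating.

`minimize()` implements the two-stage restrained relaxation protocol:
1,000 tu at HEX = 10, T = 0.7, then 1,000 tu at HEX = 0.1, T = 0.5 (the
second stage mirrors the first's duration, which is a choice this package
makes; only "short" is prescribed by common usage), with CA and CB beads
held by flat-bottom tethers of half-width 0.5 A about their input positions.

## Replica exchange

`run_rx()` runs N replicas at a strictly increasing temperature ladder; the
default is the 8-rung set 0.5246 ... 0.6862. Exchange attempts occur every
1,000 tu (production default) between adjacent rungs, alternating between
even- and odd-indexed pairs — the field-standard scheme; the pairing is a
design choice of this package. Acceptance follows Metropolis,
p = min(1, exp[(1/T_i - 1/T_j)(E_i - E_j)]); on acceptance the two replicas
swap temperature labels and rescale velocities by sqrt(T_new/T_old). Every
attempt is logged (time, pair, energies, probability, outcome). Frames are
saved every 200 tu on the global clock, so the production protocol
(1,000,000 tu) yields exactly 5,000 frames per replica, and
`demux_by_temperature()` regroups them into per-rung ensembles of exactly
the same size, each frame assigned once.

## Ensemble analysis

* **Torsions**: phi_i = dihedral(C(i-1), N(i), CA(i), C(i)), psi_i =
  dihedral(N(i), CA(i), C(i), N(i+1)), IUPAC right-handed sign, degrees in
  (-180, 180]; undefined at the termini.
* **Helical assignment**: a residue is helical in a frame iff (phi, psi)
  lies strictly inside the open window phi in (-100, -30), psi in
  (-80, -5) — chosen to bracket the canonical alpha basin, configurable
  everywhere.
* **Propensity**: the exact per-residue count ratio over frames.
* **Continuous-helix maps**: per frame, maximal runs of consecutive helical
  residues of at least `min_run` (default 4, about one turn).
* **Rg**: root-mean-squared distance of CA beads from their unweighted
  geometric centre.
* **DoS surfaces**: 2-D histogram of (Rg, E) at one temperature (default
  20 x 20 equal-width bins over the observed ranges), P normalised over
  occupied bins, DoS = -kT ln P with empty bins left undefined rather than
  zero.
* **Ramachandran occupancies**: fractions of defined (phi, psi) points in
  the helical window, the extended basin, the transition corridors AT1
  (phi in (-100, -80), psi in (-30, 30)) and AT2 (phi in (-180, -50), psi in
  (-170, -70)), the positive-phi half-plane AG, and the near-phi-zero band
  that is sterically forbidden for non-glycine residues; glycine is tallied
  separately.

Beta/extended secondary structure is deliberately *not* called: extended
torsion angles are indistinguishable from the elongated conformations in
which disordered chains spend much of their time, so only alpha-type motifs
are detectable by this analysis.

## PreSMo calling and matching

`call_regions()` reports maximal runs of residues with propensity at or
above the threshold (default 0.20), merges runs separated by at most
`max_gap` sub-threshold residues (default 0) and drops runs shorter than
`min_len` (default 4). Intervals are reported in construct numbering (the
FASTA header token `offset=N` sets the number of the first residue).
`match_regions()` marks a reference interval as detected iff a predicted
interval has both boundaries within ±2 residues, or overlaps at least half
of the shorter interval — "significant overlap" is not standardised, so the
0.5 fraction is an explicit, configurable choice. One prediction may satisfy
several references; assignment is greedy by overlap with ties to the earlier
reference. Predictions matching no reference are counted but never labelled
false positives — unobserved motifs may simply be invisible to the reference
experiment. Calling defaults to the single rung nearest T = 0.5886, with an
optional cross-temperature confirmation flag (`call_regions_confirmed()`)
for regions reproduced at an adjacent rung.

## Synthetic fixtures and what the tests show

`gen_geometry()` builds conformations with closed-form observables (ideal
helix, extended chain, collinear and ring CA arrangements);
`gen_torsion_ensemble()` draws torsion ensembles from a heterogeneous
two-state Markov chain along the chain with exact per-residue marginals and
tunable along-chain persistence, helical angles uniform inside the helical
window and non-helical angles from the extended basin; and
`gen_two_state_toy()` provides a two-bead square-well system whose
Boltzmann bound/unbound ratio, (V_well/V_out) exp(depth/T), is known in
closed form and used to verify canonical sampling of the engine.

These fixtures emulate the *statistical* structure of real ensembles —
residue-specific helical frequency with run continuity — not any real
protein: all angles are defined (including termini), non-helical residues
never visit the positive-phi or polyproline regions, and there is no
coupling between torsions and compactness. Passing tests therefore
demonstrate the correctness of the machinery (counting, calling, matching,
histogramming, sampling), not that the coarse-grained force field reproduces
any particular experimental propensity profile. Whether the shipped default
parameter set reproduces experimentally determined motif boundaries for real
sequences is explicitly untested territory.

## Problem sizes and design limits

The test and acceptance runs use reduced problem sizes chosen to give the
statistics each check needs: ladder-quality runs use a 30-residue
polyalanine for 1,500-5,000 tu (at least 50 exchange attempts per adjacent
pair at the script's settings), melting runs a 16-residue polyalanine for
3,000 tu per replica, canonical-sampling runs 30,000 tu of the two-bead toy.
Production-scale work (hundreds of thousands of tu, 50-150-residue
constructs) uses exactly the same code paths.

Known limitations: the force field is a documented stand-in, not the
published all-atom DMD parameterisations (no implicit-solvent model, no
electrostatics or salt bridges — a hook exists in the pair-table design);
kinetics are not physically interpretable; proline's backbone is not
conformationally restricted beyond its low helix weight; left-handed helix
and polyproline II propensity are not modelled; and beta-structure detection
is out of scope by construction.
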