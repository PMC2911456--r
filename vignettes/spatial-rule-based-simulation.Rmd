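---
title: "Spatial rule-based simulation with srbdyn: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial rule-based simulation with srbdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srbdyn)
```

## The modeling approach

`srbdyn` simulates rule-based reaction systems in continuous 3D space at a
coarse-grained, particle-based level of detail. The atomic unit is the
*elementary molecule* (EM): a sphere with a mass, radius and diffusion
coefficient, carrying named *components* placed on it by a length and two
polar angles. Components hold modification states and bonds; bonded EM form
*complex molecule graphs* whose position, shape and orientation are never
stored — they are implicit in the member coordinates, just as a house's
position is implicit in its bricks'.

Reactions are written as BioNetGen-style rules over *reactant patterns*:
partial molecule graphs in which unlisted components impose no constraint,
states and bond statuses can be required or left open (`~state`, `!n`,
`!+`, `!?`), and matching means subgraph embedding. Three rule kinds are
supported — *binding* (one bond formed), *breaking* (one bond deleted) and
*modifying* (one state changed) — each mono- or bimolecular. Rules that
create or annihilate molecules are rejected at parse time; molecule count
changes only through scheduled insertions.

Because rules are applied directly to the reactor contents by pattern
matching, the reachable species network is never generated: systems with
combinatorially large or unbounded species sets (polymers, lattices, tiles)
run at the cost of what is actually present.

## Dynamics

Motion integrates Langevin dynamics with velocity Verlet. Forces are

* harmonic bonds, $E = K_d\,(d - d_0)^2$, rest length equal to the sum of
  the two component lengths;
* harmonic angles at every EM with two or more bonds — one term per pair of
  bonded neighbors, $E = K_\alpha\,(\alpha - \alpha_{ijk})^2$, where the
  ideal angle $\alpha_{ijk}$ is computed from the component polar
  coordinates at compile time;
* soft-sphere repulsion $E = A\,(1 + \cos(\pi r/r_c))$ with cutoff
  $r_c = r_i + r_j$, giving volume exclusion;
* per-particle friction and Gaussian noise linked by fluctuation–
  dissipation at temperature $T$. Friction is parameterized as a damp time
  $\tau = m D / (k_B T)$ so a free particle's long-time mean-squared
  displacement is $6 D t$; both this and equipartition
  ($\tfrac32 k_B T$ per particle) are verified to 5% in the test suite.

Everything is in reduced units ($k_B = 1$, unit mass/length/energy). The
one deliberately SI-facing helper is `timestep_worked_example()`, which
maps a hemoglobin-sized particle through Stokes–Einstein to a physical time
step (about half a nanosecond when the per-step translation is a tenth of a
diameter) and a total simulated time (1.5 ms for $3\times10^6$ steps).

Numerical choices worth knowing:

* the angle gradient is clamped near collinearity ($\sin\alpha \ge 10^{-4}$),
  where the harmonic angle force is otherwise singular;
* periodic boundaries use minimum image; reflecting walls flip position and
  velocity; rigid groups are never wrapped member-by-member, only remapped
  as a whole;
* rigid groups (declared per species set in the geometry file) move as
  rigid bodies: member forces are summed into a net force and torque, the
  world-frame inertia tensor is solved each step, and members are rotated
  exactly (Rodrigues), so intra-group distances are preserved to floating
  point accuracy. Intra-group bonded and pair forces are skipped.

## Reactions

After every integration step the rule system evaluates the interval
$[t, t+\Delta t)$; particle movement inside the step is not considered.

*Monomolecular* rules run through a fragmented Gillespie algorithm on the
occurrence counts of their reactant patterns: waiting times are sampled
from the summed propensities, events execute on a uniformly chosen matching
molecule while the sampled time stays inside the step, and the fragmentation
across steps is exact because exponential waiting is memoryless (verified
against a direct-method SSA by a two-sample KS test at $10^4$ events).

*Bimolecular* rules fire between neighbor pairs closer than a threshold
`sigma` (validated at startup to exceed every rule's ideal bond length plus
distance tolerance). A candidate pair must anchor the rule's two reactant
patterns on molecule-disjoint embeddings — two subgraphs of one complex
count, which is how scaffold-bound ligands keep reacting at the solution
rate while co-localization raises their encounter frequency — and must be
*geometrically compatible*: center distance within `t_dist` of the ideal
bond length, and, for each already-bonded molecule, the direction to the
candidate within `t_ang` of the ideal angle against the direction to every
bonded partner. Unbound molecules carry no orientation and impose no
angular condition. Compatible candidates fire with probability
$1 - e^{-k\,\Delta t}$; candidates are evaluated in random order and a
molecule reacts at most once per step. Angular tolerances are per species,
with optional per-component overrides in the geometry file (`angtol`) —
used where one interface needs a tight geometric gate and another a loose
one.

Rates in model files are microscopic per-pair rates. The macroscopic
connection is the contract of `convert_macroscopic_rate()`:
$k_{2mic} = k_{macro} / V_{react}$, where the reactive volume comes from
`reactive_volume()` (closed-form spherical shell for unbound partners;
Monte-Carlo integration under angular constraints otherwise). The test
suite closes the loop: a dilute well-mixed binding run recovers the input
macroscopic rate within 15%, and reversible dimerization matches a
well-mixed SSA equilibrium within 10%.

After a breaking event both endpoint molecules become *refractory*
(default $10\,\Delta t$): no new binding until the clock passes, giving the
pair time to separate by diffusion instead of instantly re-binding. The
suite verifies that rebinding within ten steps drops monotonically with the
refractory length.

*Caching.* All reactant patterns are enumerated at compile time; every EM
caches the indices of patterns it anchors. After a reaction only molecules
within the maximum pattern graph diameter `d_max` of the touched molecules
are re-matched; equality with a full recomputation is asserted over more
than a thousand randomized events. Occurrence counting offers two modes —
`per_embedding` and `per_molecule_graph` — because a pattern like an A–B
edge appears twice by embedding but once by complex in an A–B–A trimer;
observables default to per-embedding counting, and symmetric patterns count
each unordered embedding once (the package does not apply a symmetry rate
factor; the alternative convention would double symmetric-rule propensities).

## The example systems

Four generators build complete model/geometry/config bundles. Their
parameters are the package's own reconstructions: rates, counts and angles
were chosen once to make the described mechanism operate at desk scale and
are not fitted to any published curve. Runs use a few thousand to a few
tens of thousands of steps and 50–350 particles so each completes in
roughly a minute or two on one CPU.

**Scaffold** (`fixture_scaffold()`): particles A phosphorylate each other on
contact and dephosphorylate over time; scaffolds S bind up to four A at rate
`k_s` on four components facing one pole. Angular tolerance is 180° (bonds
accepted from any direction) and the angular force is off, so bound A
diffuse over the scaffold surface. With `k_s = 0` the binding rule remains
at rate zero. The emergent result — higher steady phospho-levels with
active scaffolds, without any scaffold-specific rate in the model — is
tested as an ordering across ten seeds (one-sided rank test), because it is
a qualitative claim.

**Microtubule** (`fixture_microtubule()`): tubulin heterodimers assemble
onto a fixed nucleating structure into a 13-protofilament tube with the
13_3 lattice — three subunit layers of rise per lateral turn, hence a seam
where alpha binds beta laterally. (A rise of three *dimers* per turn would
put alpha next to alpha and produce no seam; the package follows the
3-start subunit helix that the seam requires and reports rise in subunit
layers.) Design choices that matter here:

* *Nucleating collar.* The structure is the 13-member capping ring plus one
  pre-wired dimer layer, open at the wrap. A bare ring cannot transmit the
  helical register through the purely local angular tests, for the same
  reason the level of detail cannot constrain torsion around a bond: both
  registers of a lateral contact differ only by 26.6° at one bond. The
  collar presents the register the way a templating ring complex does; the
  seam and all further layers assemble from solution.
* *Template-gated growth.* Elongation requires a lattice-attached column
  top and lateral zipping requires lattice-attached partners, so solution
  oligomers do not scramble the register (spontaneous nucleation is
  suppressed, as it is for the biological counterpart).
* *Per-component tolerances.* Lateral sites keep an 18° window — below the
  26.6° register discrimination — while longitudinal sites get 30°, since
  attachment geometry is subsequently straightened by the angle forces.
* *Helicity measurement.* `seam_and_helicity()` walks single lateral steps
  once around the tube and reports the accumulated axial offset; defect
  bridges (multi-step or same-azimuth contacts) are excluded, and the walk
  necessarily crosses the seam. On hand-built reference lattices the walk
  returns exactly 0 (a 13_0 test lattice) and 3 (13_3).
* Kinesin stepping and cargo handling occupy the remaining 14 rules; motor
  directionality is geometric (the motor site on beta tilts toward the
  minus end, so only the plus-ward site is angularly reachable for the free
  head of a bound pair). Motors and cargo insert in a second phase.

**Spheres** (`fixture_spheres()`): rigid six-EM monomers — an outer and an
inner triangle — bond same-type-to-same-type with outer components of
length 1.4 and inner of 1.0; the bond-length mismatch curves the growing
sheet into shells whose rings are counted by `ring_census()` (verified
against known truncated-icosahedron combinatorics). Eight rules in four
rate pairs: free coupling, addition to a complex, and two dissociation
behaviours.

**Sierpinski tiles** (`fixture_sierpinski()`): four tile species encode the
XOR truth table with two down (input) and two up (output) binding sites;
the two 0-output tiles are distinct species. Tiles attach above a fixed
seed row in two bimolecular steps because only one bond can form per
reaction event; single-bonded tiles dissociate quickly. The reference
pattern generator iterates `c[r][i] = c[r-1][i-1] XOR c[r-1][i+1]` and
equals Pascal's triangle mod 2 for a single-1 seed; the extractor snaps
attached tiles to the half-spacing grid and counts mismatches, which are
assembly errors to report, not failures.

## What the generators do and do not emulate

The fixtures regenerate the *described structure* of the example systems —
species, component layout, rule organization, counts — not any lost
original input files; equivalence is checked by emergent-structure analyses
(protofilament count, seam and rise, ring census, tile pattern, rule
censuses) and not by byte comparison. Geometric parameters are qualitative
reconstructions. Consequently a passing suite demonstrates that the
*method* reproduces the described emergent behaviours at reduced scale; it
does not validate quantitative kinetics of any real protein system, and
features the originals may have had (exact rates, full 600-dimer boxes,
longer horizons) are replaced by scaled equivalents chosen for minute-scale
runs.

## Known limitations

* No torsional (dihedral) constraints and no rotational state on unbound
  EM — helical handedness is not locally expressible, which is exactly why
  the filament fixture uses a registered collar. Complex building blocks
  (the six-EM monomer) are the supported workaround.
* Exchange rules (molecule creation/annihilation) are not supported;
  insertion is scheduled-only, deletion absent.
* One bond per component, at most one new bond per reaction event;
  trimolecular mechanisms must be decomposed, as the tile fixture does.
* `K_d`, `K_alpha` and the repulsion height are global per run, not
  per bond type.
* Movement within a step is invisible to reaction detection, so `sigma`,
  tolerances and `dt` must be chosen together; the startup validator
  enforces the reachability constraint.
* The spatial engine is single-threaded; desk scale is a few hundred EM
  for tens of thousands of steps per minute of wall time.
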