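---
title: "Models, numerics and design choices in hairpinscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, numerics and design choices in hairpinscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairpinscape)
```

This vignette records how the package's three analysis tiers are
modelled, which numerical and design choices were genuinely open, and
what the synthetic generators do and do not emulate.

## 1. Geometric classification

### The ξ coordinate

The families of the hairpin's top half are separated by a pseudo-angle
ξ measured between the bulged probe base U40, the apex base pair
A43–U66, and the distal base pair C45–G64. The literature defines the
angle by these residues but not by specific atoms. We realize it with
**base-ring centroids**: the vertex is the midpoint of the two apex-pair
ring centroids, and the angle is taken between the directions to the
probe's ring centroid and to the midpoint of the distal-pair centroids.
Ring centroids are invariant under rigid motion, insensitive to missing
hydrogens, and robust to individual atom displacements (they average
6–9 atoms). The reference residues are configurable through
`angle_spec()` for non-wild-type numbering. A consequence of the
centroid realization is quantitative: an in-plane triplet at the distal
pair corresponds to ξ near 45–50°, so the compact-family builder tilts
U40 slightly above the distal pair plane to land near the canonical
30° (see §4).

### Band boundaries

The published band descriptions overlap at 60° and 100°. We resolve
both boundaries downward — [0, 60] → M1, (60, 100] → M2,
(100, 180] → E — so that classification is a deterministic, total
function; the boundary value belongs to the more compact family. An M2
assignment is refined to M2\* when the U63·U44–A65 triplet is
detected; we use the triplet criterion alone (no energy criterion),
because the state is experimentally characterized as a subset of M2
with that additional interaction.

The in/out state of the gatekeeper base U63 uses the angle
U44–A65–U63 with a default threshold of 100° (boundary counts as
"out"). The threshold is not fixed by any published analysis — the
published projection is unthresholded — so it is exposed as an
argument.

### Hydrogen bonds, pairs and triplets

No published hydrogen-bond criteria accompany the counts quoted for
these systems, so the defaults follow common structural practice:
donor–acceptor heavy-atom distance ≤ 3.5 Å, plus a D–H…A angle
≥ 120° whenever an explicit hydrogen rides on the donor
(crystallographic heavy-atom structures fall back to the distance
criterion). Donor/acceptor assignments for A, C, G, U and the twenty
amino acids ship as a plain-text table in `inst/extdata/`.

Base pairs require at least two **inter-base** hydrogen bonds whose
bond vectors run within 45° of both base planes. The in-plane
condition is essential: at A-form stacking distances (2.8 Å rise) polar
atoms of stacked neighbours routinely satisfy a pure distance
criterion, and only the bond-direction test separates edge-to-edge
pairing from stacking. Pairs must additionally have ring-centroid
separation ≤ 7 Å and base planes within 35° (admitting propellered
pairs). Triplets are canonical third-base additions (T1, T2, T3 and
the U63 marker); presence requires the pair plus at least
`min_support = 2` inter-base bonds from the third base to the pair
members — two is the canonical count for U·A–U and U·C–G additions.
Non-canonical bases joining a detected pair at the same support level
are reported as `OTHER`; because support is distance-based, stacked
neighbours of a pair can appear there, which is why family logic never
consumes `OTHER` rows.

## 2. Kinetic transition networks

Thermodynamics uses the harmonic superposition of minima:
$p_i \propto \exp(-E_i/k_BT)$, extended by vibrational
frequency-product and symmetry-number factors when the database
provides them for *all* minima (mixing weighted and unweighted minima
would bias populations, so that case is an error). Every Boltzmann sum
is evaluated in the log domain (log-sum-exp); free-energy gaps of
tens of kcal/mol are exact with `kB = 0.0019872` kcal/(mol·K).

Rates use harmonic transition-state theory,
$k = \nu\,e^{-(E_{ts}-E_{min})/k_BT}$, with a uniform attempt
frequency ν = 10¹³ s⁻¹ when frequency data are absent. Published
stationary-point databases rarely include the vibrational products, so
absolute rates carry the prefactor uncertainty; ratios, detailed
balance and route-equivalence do not, and those are what the tests
assert. The forward/backward ratio over one transition state follows
from the definition: $k_{12}/k_{21} = e^{-(E_2-E_1)/k_BT}$ — the
uphill direction is slower.

Inter-funnel rates are computed two ways. The `"master"` route builds
the full rate matrix, symmetrizes it with $\sqrt{p}$ (exact under
detailed balance), takes the slowest nonzero relaxation eigenvalue
λ₁ and splits it two-state: $k_{ab} = \lambda_1 P_b$,
$k_{ba} = \lambda_1 P_a$, with equilibrium weights restricted to the
two sets. The `"gt"` route eliminates all intervening minima by graph
transformation (renormalizing branching probabilities and waiting
times) and forms steady-state rates on the reduced network. Both
satisfy detailed balance identically; they agree only under
**time-scale separation** (intra-funnel relaxation much faster than
exchange), which is also the regime in which a two-state description
is meaningful at all. Two numerical facts bound the regime from both
sides:

* the two-state systematic error scales as λ₁/λ₂ (exchange over
  slowest intra-funnel relaxation), requiring roughly ≥ 6 decades of
  separation for 10⁻⁶ agreement;
* a dense symmetric eigensolver delivers eigenvalues to absolute
  accuracy ~ε‖K‖, so λ₁ is *relatively* accurate only while it stays
  within ~10 decades of the fastest mode.

The planted-network generator is therefore built to produce landscapes
inside that window (§4). Outside it — for example a landscape with a
14 kcal/mol inter-funnel gap — the ratio
$k_{ab}/k_{ba}$ remains exact (detailed balance) even where the
eigensolver's absolute λ₁ is floor-limited, which is why the
acceptance script reports the rate *ratio* for the large-gap showcase
and route-equivalence on separated networks.

Basin content under a cutoff selects minima connected to a designated
bottom through transition states no higher than the bottom energy plus
the cutoff (default 15 kcal/mol), restricted to minima below that
energy, and reports family composition both uniformly and
Boltzmann-weighted — published basin percentages do not state which
weighting was used, so both views are emitted.

## 3. Disconnectivity graphs and funnels

The superbasin tree is built by union-find over transition states
below a descending sequence of thresholds (default spacing
1 kcal/mol, a figure-scale granularity). Leaves terminate at their
minima energies; the lowest-common-ancestor level of any two minima is
an upper bound on their true minimax barrier and lies within one
spacing of it. Funnel membership is defined by **minimax-path
attraction**: each minimum belongs to the designated bottom reachable
over the path whose highest transition state is lowest, ties going to
the lower-energy bottom; the minimax barrier is computed on the
minimum spanning tree of the barrier-weighted graph, where it is
exact. This makes "funnel" a reproducible, oracle-checkable notion
rather than a visual one. SVG rendering orders subtrees by member
count (deterministically), colors leaves by family (M1 blue, M2
green, M2\* dark green, E red) and is byte-reproducible.

## 4. The synthetic generators

The generators exist to give every analysis stage inputs with known
ground truth. They are geometric constructions, **not** energy
minimized, and three deliberate distortions matter for interpreting
test results:

* **Planted hydrogen bonds are compressed to 2.50 Å** (crystallographic
  averages are 2.8–3.0 Å). Under the default coordinate jitter
  (σ = 0.3 Å per coordinate, hence pairwise-distance noise of
  sd √2·σ ≈ 0.42 Å), a planted contact must sit ~2.4 sd inside the
  3.5 Å detection cutoff for planted pair/triplet patterns to survive
  jitter reliably; at crystallographic lengths the patterns would
  decay at a few percent per bond, which is a property of distance
  thresholds under noise, not of the detectors.
* **The apical loop (49–59) is a crude outward-facing arc.** The
  native loop is replaced even in the experimental constructs, and no
  test consumes loop geometry; loop-loop contacts can appear in raw
  hydrogen-bond lists.
* **Backbone continuity is approximate** across bulges and between
  stacked pair blocks; intra-residue covalent geometry is within ~10%
  of standard values, inter-residue linkage is not guaranteed.

The hairpin builder stacks ideal Watson–Crick pair blocks (twist
32.7°, rise 2.81 Å) for the three stem pairs, the GAUC/GAUC helix and
the upper stem, then places the bulges per family: Hoogsteen-edge
planting of U40 (T2) or U41 (T3) solves a one-parameter spin equation
so both planted bonds hit their targets; the M1 template tilts U40
~42° above the C45–G64 pair ("adjacent to the pair plane") which
simultaneously realizes T1 and ξ ≈ 30° under the centroid
realization; the extended template extrudes the bulges along a
direction making the target ξ ≈ 150° with the apex midpoint. In the
open-groove templates (M2 with U63 out) the free bulges are steered to
the azimuth opposite the major-groove track — the accessibility of the
groove is the defining feature of that state. Seeds perturb placement
angles by a few degrees; the same seed is bit-reproducible, and no
generator touches the caller's RNG stream.

Mixtures use largest-remainder rounding of `n · fractions` (the truth
payload records the exact planted counts) and a seeded shuffle.

Planted networks draw each funnel as a random tree with
bottom-relative, shifted and truncated exponential energy increments
(floor 0.3 kcal/mol, truncation at 2.5 scales; transition states
1.0 kcal/mol plus a truncated exponential above the higher adjacent
minimum), joined by single transition states at `inter_barrier`
(default 15 kcal/mol). The floors and truncations bound the
intra-funnel relaxation band so that inter-funnel exchange is cleanly
separated — the regime discussed in §2. Draws repeat (seeded) until
every intra-funnel barrier lies below the joining barrier.

Peptide poses place the HEXIM1 arginine-rich motif against the
GAUC/GAUC helix. The groove pose coils the backbone along the helical
track (twist-per-rise locked to 32.7°/2.81 Å so the chain keeps a
constant azimuthal offset from the backbone ridges; per-residue rise
then follows from the 3.8 Å CA–CA virtual bond), charged sidechain
tips pointing inward, with the azimuthal phase chosen at each radius
to maximize clearance and the radius grown until no heavy-atom pair is
closer than 2.2 Å. The surface pose is a straight rod resting
tangentially on the backbone shell with sidechains pointing away, and
retracts until **van der Waals contact** (no interpenetration of vdW
spheres) rather than the 2.2 Å clash floor — a docked pose may
interdigitate; a surface contact rests on the spheres. This
distinction is what makes the groove pose systematically snugger
(smaller gap index) across seeds. The distant pose shifts the rod to
a 50 Å minimum separation.

## 5. Peptide–RNA interface numerics

Solvent-accessible surface areas use Shrake–Rupley with 960
deterministic Fibonacci-lattice points per atom and a 1.4 Å probe;
buried area is `(SASA_A + SASA_B − SASA_AB)/2`. The gap index divides
the gap volume by that buried area. The gap volume is measured on a
cubic grid (default 0.8 Å): cells outside both vdW surfaces, within
4.0 Å of both chains, and *between* them. Betweenness is decided by
the directions to the nearest atom of each chain opposing each other
(negative dot product): a neighbourhood-based nearest-chain flip rule
marks only a watershed sheet whose volume scales with the grid
spacing, whereas the opposing-directions rule converges under grid
refinement (the tests assert 0.8 vs 0.4 Å agreement within 15%). The
reference gap-index procedure is published without parameters, so
these constants are explicit package choices; conclusions are drawn
from orderings between poses, never from absolute values.

The Coulomb energy uses a formal-charge model at pH 7 — phosphate −1
split over OP1/OP2, Lys/Arg +1 (Arg split over NH1/NH2), Asp/Glu −1,
charged termini — with `E = 332.06 Σ q_i q_j / (ε r_ij)` kcal/mol and
a uniform dielectric of 78.5 (water). Force-field energies of the
original simulations are not reproducible from coordinates alone; the
model supports relative comparisons between poses of the same
complex, which is all the package claims.

## 6. Problem sizes and what the tests show

The test-suite defaults are sized for laptop-scale runs: mixtures of
500 frames across 20 seeds for composition recovery, 150 jittered
fixtures for triplet-pattern stability, 100 planted networks (≤ 20
minima) for route equivalence, exhaustive oracles on networks of ≤ 12
minima, and three seeds per peptide-pose comparison.

Passing these tests demonstrates that the implementations are correct
against independent oracles and that planted signals are recovered
under the generators' noise model. It does **not** demonstrate that
the default thresholds reproduce any particular experimental count on
real structures: hydrogen-bond counts on deposited models depend on
criteria the original analyses did not publish, absolute rates depend
on unavailable vibrational data, and the synthetic fixtures are
idealized. `deposited_model_checks()` applies the identical pipeline
to a locally supplied PDB file of the deposited models for users who
want the accession-dependent numbers.
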