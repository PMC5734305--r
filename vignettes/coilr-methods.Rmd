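---
title: "Parametric coiled-coil modeling with coilr: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric coiled-coil modeling with coilr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilr)
```

## The model

A coiled coil is a bundle of α helices wound around a common super-helical
axis. coilr describes each helix by the classical Crick parameters:

* **radius** `r` (Å) — distance of the helix's own axis from the
  super-helical axis;
* **pitch** `P` (Å) — axial distance for one full super-helical turn; the
  sign encodes handedness (negative = left-handed, the natural sense for
  heptad-repeat coiled coils). The pitch angle is
  `α = atan(2πr / P)`;
* **interface angle** (Crick angle at `a`, degrees) — the azimuth of the
  reference register-`a` CA about the helix's own axis, measured from the
  direction pointing at the super-helical axis;
* **super-helical rotation** (degrees) — the helix's angular offset about
  the assembly axis; the symmetric default for helix `i` of an `n`-mer is
  `(i − 1)·360/n`;
* **z-shift** (Å) and **orientation** (parallel / antiparallel) for
  slipped and antiparallel topologies.

A chain is generated by sweeping a minor helix along the super-helical
path. The CA minor helix uses rise 1.495 Å per residue, minor radius
2.26 Å and a phase advance of exactly 720/7 ≈ 102.86° per residue *in the
rotating (Crick) frame*. The rotating-frame convention makes a heptad span
exactly two minor-helix turns, so `a`/`d` positions keep a constant Crick
angle along the chain and form continuous hydrophobic seams at any pitch.
The flip side is that in the uncoiled (infinite-pitch) limit the helix
shows 3.5 residues per turn rather than the ~3.6 of an isolated α helix;
we consider this the right trade-off for a coiled-coil engine, since the
supercoil normally absorbs exactly that twist difference.

N, C and O are placed on their own minor helices: their radius, phase and
axial offsets *relative to CA* are derived at load time from an ideal
straight helix built from canonical internal coordinates
(φ = −57.8°, ψ = −47°), in the spirit of the classical backbone-generation
schemes. Collagen strands use the same machinery with polyproline-II-like
constants (rise 2.86 Å, minor radius 1.63 Å, left-handed 3.5-residue
turn, i.e. 7/2-inspired symmetry) and a right-handed triple-helical path;
`O` in a collagen sequence becomes 4R-hydroxyproline (HYP).

### Conventions that had to be pinned down

* **Angles** are stored on [−180°, 180°) and exposed in degrees;
  coordinates are Å in a right-handed frame with the super-helical axis
  along +z.
* **Antiparallel chains** run N→C down the axis with residue 1 at the top
  of their z-range, and the z-shift is applied after the orientation
  reversal. The super-helical rotation of *any* chain is defined as its
  azimuth where it crosses its own z-shift plane (residue 1 for parallel,
  residue n for antiparallel chains). With this convention a dimer built
  at rotations 0°/180° is symmetric at every height regardless of
  orientation mix; referencing the rotation at residue 1 instead would
  make an antiparallel partner spiral away from its intended position by
  the accumulated super-helical phase.
* **z-shift is decoupled from azimuth**: shifting a chain axially
  translates it rigidly and does not rotate it. This keeps all parameters
  independent, at the cost that a "slipped" topology needs an explicit
  rotation if the user wants the shifted chain to stay on the original
  super-helical track.

## Measuring parameters back from coordinates

`measure_parameters()` inverts the builder. A 7-residue boxcar over the
CA trace cancels the 102.86°/residue minor helix exactly (the seven
phases form a complete set of 7th roots of unity), leaving points on the
super-helical path. The global axis is initialized from the average of
the chains' path chords — for symmetric bundles the radial components
cancel, which is markedly more robust than a principal-components axis
when chains sweep short, strongly inclined arcs. Each chain is then
refined by Levenberg–Marquardt least squares against the full Crick CA
model, with four starts over the Crick phase (the residual surface is
sinusoidal in it) and both an axis-fixed and a free-axis refinement (the
axis-fixed fit avoids a radius/tilt degeneracy at large pitch angles).
Radius, pitch and interface angle are rigid-motion invariant; the
reported super-helical rotation and z-shift are relative to the fitted
frame, so only their differences between chains are meaningful. A chain
whose coarse-stage |pitch| exceeds 1000 Å (or whose path collapses onto
the axis) is reported as uncoiled, with `pitch = NA`.

## Knobs-into-holes analysis

`find_kih()` implements the classical packing criterion: a residue is a
*knob* into a partner chain when at least four side-chain centers
(centroid of side-chain heavy atoms including CB; CA for glycine) on that
chain lie within the packing cutoff (default 7.0 Å, the established
value) of its own center; the four nearest form the *hole*. A knob is
*complementary* when the partner chain reciprocates with a knob whose
hole contains it; chain ends are excluded from knob candidacy.
Orientation is read from the local helix-axis dot product.

`assign_register()` labels knobs `a` or `d` by their Crick angle in the
fitted super-helical frame — `a` within half a phase step (51.4°) on the
positive side of the core-facing direction, `d` on the negative side —
and fills the rest of each chain's register by heptad periodicity, with
the confidence given by the fraction of labeled knobs consistent with the
winning phase. An earlier design that used raw local vectors (side-chain
direction against the knob-to-hole direction) carried systematic offsets
of tens of degrees from rotamer tilt and hole asymmetry and mislabeled
antiparallel interfaces; the fitted Crick angle is exact for parametric
models and rigid-motion invariant.

## Side-chain placement

The internal placer exists so that the build → pack → score pipeline is
testable hermetically; it is not a combinatorial packer. Every residue is
placed at its single most-populated backbone-independent rotamer using
ideal internal coordinates (frozen, with chi parameterization, in
`extdata/sidechain_geometry.tsv`), then up to three greedy passes cycle
residues involved in inter-residue clashes (< 2.0 Å heavy-atom) through
a couple of alternative rotamers. Hydrogens are never placed. A
SCWRL4-compatible external packer can be hooked in
(`strategy = "external_packer"`); its absence or failure is a loud error,
never a silent fallback.

## The interaction score

The optimization objective is a soft-core, heavy-atom, strictly
inter-chain pair potential with three terms, reported in arbitrary units:

* **steric** — quadratic finite repulsion inside the contact distance
  (sum of the two atom radii), with a linear well of depth 0.15 a.u.
  reaching zero 2 Å past contact;
* **desolvation** — −0.35 a.u. per buried hydrophobic–hydrophobic pair
  (side-chain carbons), decaying over 2.5 Å past contact;
* **charge** — a distance-shifted screened Coulomb term on formal
  charges (+1 Lys NZ / Arg CZ, −1 on the Asp/Glu carboxylate carbon as a
  midpoint convention, His neutral), zero at the 10 Å cutoff.

Every term reaches exactly zero at or before the cutoff, so the energy is
continuous in the coordinates, and the total is additive over unordered
chain pairs. Atom radii use a united-atom, pair-minimum convention
(C 2.0, N 1.75, O 1.70, S 2.05 Å): with implicit hydrogens the well
bottom of a carbon–carbon contact belongs at ≈ 4.0 Å. The constants were
calibrated once so that the canonical Ile@`a`/Leu@`d` dimer has its
energy minimum at radius ≈ 4.9 Å — the physically observed dimer radius —
and are all exposed through `scoring_constants()` and the versioned
plain-text parameter table, so substituting a published force-field
parameterization changes data, not code. Neighbour search is a dense
per-chain-pair distance block, which is the right tool at desk scale
(≤ a few thousand atoms); a cell list would pay off only far beyond the
assembly sizes this engine targets.

## Metropolis Monte Carlo optimization

`optimize_parameters()` runs a Metropolis chain over (radius, pitch
magnitude, interface angle) for basic-mode assemblies: one uniformly
chosen parameter is perturbed by a Gaussian step, clamped to bounds, and
accepted when the energy does not increase, otherwise with probability
`exp(−ΔE/T)`. Requests are capped at 300 residues across all chains
(overridable off-web with `allow_large = TRUE`), and only basic-mode
specifications are accepted. Each step rebuilds the backbone and places
side chains at the primary rotamer (no clash cycling), keeping the
objective a deterministic, smooth function of the parameters — the
soft-core potential is finite in clashes, so clash cycling would only add
noise to the ranking. The internal fast path is asserted in the
test-suite to agree exactly with the public
`build → place_sidechains(max_passes = 0) → interaction_energy` pipeline.

Defaults (T = 8 a.u., steps 0.3 Å / 10 Å / 8°, 500 steps) were chosen for
reliable recovery at desk scale. Two features of the objective forced two
deliberate deviations from a textbook sampler:

* beyond contact the inter-chain energy is exactly zero, so a chain that
  wanders outward performs an unbiased random walk with nothing to pull
  it back. A **best-so-far restart every 300 steps** (a basin-hopping
  ratchet) bounds those excursions;
* the canonical dimer objective has a secondary basin near r ≈ 6.2 Å;
  T = 8 with 8° interface-angle steps crosses the barrier reliably
  within ~1500 steps.

The `metropolis_run()` kernel itself defaults to a pure Metropolis chain
(`reset_every = Inf`); the acceptance-rule correctness is tested on a
frozen quadratic objective against `exp(−ΔE/T)` at 10⁴ trials, and the
ratchet never runs in that configuration. `scan_oligomer_states()`
repeats seeded optimizations across oligomeric states and compares the
best energy *per helix* — without the normalization larger bundles would
win trivially by having more interfaces. Sequences with Ile at `a` and
Leu at `d` come out as low-order (dimer/trimer) assemblies, as expected.

## The synthetic examples and what passing tests show

`example_specs()` generates the canonical topologies end-to-end: parallel
homotypic dimer–heptamer, an antiparallel homodimer, a slipped heptamer,
A4/B4 and A3/B4 acidic/basic heterodimers, and homo/heterotrimeric
collagens. The homotypic parameters are the engine's own canonical
states — the interaction-energy optima for the Ile@`a`/Leu@`d` heptad
(dimer 4.9 Å / −130 Å / 19°, trimer 6.4 / −170 / 16°, tetramer at the
experimentally typical 6.8 / −213 / 15°, barrels widening from 10 Å) —
so built fixtures genuinely pack (every coiled-coil fixture shows
knobs-into-holes contacts). The collagen fixtures use three symmetric
strands (radius 3.0 Å, pitch 85 Å) with the phase reference at −90° so
the glycine edge faces the core.

These generators emulate ideal parametric geometry with a fixed rotamer
per type. They do not emulate real-data features: side-chain rotamer
heterogeneity, helix fraying at termini, non-canonical repeats (the
per-residue phase advance is overridable via the `constants` argument but
not exercised), solvent, or crystallographic noise. Passing the
round-trip and packing tests therefore demonstrates internal consistency
of the engine and correctness of its geometry and bookkeeping — not that
fitted parameters from experimental structures will reach the same
accuracy.

## Problem sizes used in the shipped checks

The shipped tests run 4-heptad chains (28 residues per helix, 2–7
helices), a 5×5 (radius, pitch) round-trip grid, 10⁴-trial acceptance
statistics for the Metropolis rule, and ten seeded 1500-step recovery
runs of the canonical dimer; these sizes were chosen as the smallest at
which each property is sharply testable.

## Known limitations

* Backbone bond lengths deviate by a few hundredths of an Å from ideal
  values when the minor-helix offsets (derived at the ideal α-helical
  twist) are used at the heptad-averaged 102.86° phase advance; the CA
  trace is unaffected.
* The internal rotamer placer is deliberately minimal; models intended
  for anything beyond relative scoring should be re-packed with a real
  side-chain packer through the external hook.
* The interaction score is a documented stand-in with calibrated
  constants, suitable for ranking and optimization, not for absolute
  energetics; energies are reported in arbitrary units on purpose.
* Register assignment assumes heptad periodicity; hendecad and other
  non-canonical repeats are out of scope.
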