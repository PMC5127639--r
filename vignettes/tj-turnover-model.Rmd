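---
title: "The f-TKD turnover model: geometry, dynamics and measurement"
author: "ftkd package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The f-TKD turnover model: geometry, dynamics and measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftkd)
```

## The problem

The epidermal tight-junction (TJ) barrier is a single-layered honeycomb of
sealing belts formed by the SG2 cells of the stratum granulosum.  Cells
continuously differentiate upward through this layer, so the barrier must
be locally torn down and rebuilt without ever leaking.  This package
implements a cell-resolved model of that process: granular cells are
flattened Kelvin tetrakaidecahedra (f-TKD) stacked in the interdigitated
space-filling packing, and a small set of local rules governs when a cell
leaves the barrier and how its TJ polygon is replaced by the one of the
cell below.  The package simulates the dynamics, extracts the en face TJ
honeycomb with bicellular/tricellular (bTJ/tTJ) seam classification,
audits barrier continuity, and applies the same morphometric procedures
one would apply to en face microscopy.

## Cell and lattice geometry

The canonical cell is the truncated octahedron with vertices at all
coordinate permutations of $(0,\pm1,\pm2)$ (24 vertices, 36 edges, 8
hexagonal + 6 square faces, volume 32).  A rotation takes the body
diagonal $(1,1,1)/\sqrt3$ to the stacking axis $z$, and $z$ is scaled by a
flattening ratio $f$.  Space is tiled by the body-centred-cubic packing,
realized here as vertical *columns* of cells stacked through their
apical/basal hexagons.  Column centres form a triangular lattice; each
column touches six lateral columns, and toward each of them a cell
presents one hexagonal face and one square face (one above, one below the
equator).  Column height phases advance by one third of a stacking vector
per lattice step, so the six lateral stacks around any column alternate
up/down — every cell has 14 face-sharing neighbours and exactly 3
higher and 3 lower nearest lateral cells.

**Flattening ratio.** Nothing in the en face honeycomb depends on $f$ (it
only scales $z$), and granular-cell flattening is not quantified by
available measurements; the default $f = 0.25$ gives the familiar
flattened profile and is configurable.

**Micrometre scale.**  One en face scale factor converts lattice units to
µm.  The default anchors the ideal crystal's mean single-edged polygon
area (the Voronoi tile, $16/\sqrt3$ units²) to the reference 905.8 µm²;
`calibrateScale()` refines the factor so that any given honeycomb's
*measured* steady-state mean hits the target, which is the convention used
for reported areas.

## The TJ ring on a cell

TJs run along the apical edges of SG2–SG2 contact faces.  Toward a
*higher* neighbour the contact is the upper face of the sector and its
apical edge lies near the cell's apical hexagon; toward a *lower*
neighbour it is the lower face, whose apical edge lies at the cell's
widest extent.  Consecutive sector edges are joined along the unique
monotone path on the shared sector-boundary chain of the polyhedron —
this join rule is the package's explicit formalization of ring paths that
are otherwise only drawn in cartoons.  The 64 possible
higher/lower configurations give 64 precomputed ring templates:
all-lower is the maximal 12-edge cross-section circuit (en face area
$8\sqrt3$ units², the cell silhouette), all-higher is the apical hexagon
($3\sqrt3$ units²), and mixed configurations interpolate.  Because both
cells of a contact agree on the face, and hence on its apical edge,
adjacent rings share seams exactly and the single-plus-exterior polygons
tile the plane with neither gaps nor overlaps — a property the tests
verify numerically.

## Turnover dynamics

Three local rules drive turnover:

1. bTJs form on edges shared by two SG2 cells; tTJs form on edges shared
   by three (this is handled at extraction time, not in the state).
2. An SG2 cell higher than all six adjacent SG2 cells differentiates to
   SG1 after a waiting time drawn uniformly from $[0, 9.6]$ hr.
3. The SG3 cell below is promoted to SG2 synchronously with that
   differentiation.

The engine is discrete-time with a 7.2-min frame interval (deadlines are
quantized to frames).  "Higher" is tracked through entry times: on the
interdigitated lattice the height order of adjacent SG2 cells provably
equals their age order, and the extractor re-checks this equivalence on
every snapshot (`auditHeights`).

**Who counts as the column's SG2 cell during a transition?**  Rule 3 says
the old cell differentiates at the moment the new one is promoted, i.e. at
the transition *start*.  Eligibility comparisons therefore see the young
incoming cell from that moment, while the exiting cell — whose TJ takes
2.4 hr to disappear — continues to define the column's top for honeycomb
geometry until the transition completes.  The alternative convention
(neighbours blocked until the transition completes, comparisons against
the exiting cell) was implemented and rejected: it throttles the dynamics
to a ~66 hr emergent period and a ~3.6% double-edged share, far from the
calibrated regime.  Under the convention used here, two adjacent columns
can occasionally (≈2% of column-frames) be mid-transition at the same
time; the geometry remains consistent (the exterior ring follows the
current neighbour-top configuration) and relative-Z statistics are, as in
the reference measurements, restricted to double-edged polygons surrounded
by six single-edged ones (`tjOctets`).

**Waiting is non-preemptive** (a started clock runs out), which is
immaterial in practice because a locally highest cell cannot lose that
status before transitioning — a neighbour would have to be higher to act.

**Phases.**  A steady column shows one single-edged polygon.  During the
2.4-hr transition (phase 1) the column is double-edged: the exterior
polygon is the exiting cell's ring, and the interior polygon is the apical
hexagon of the incoming cell, every edge of which is shared by exactly
three SG2 cells (incoming + exiting + one lateral), hence all-tTJ.  At
completion (phase 2) the exterior polygon disappears and the interior —
whose seams are now shared by two cells only — becomes the column's
single-edged bTJ polygon.  The interior forms before the exterior goes:
this overlap is what keeps the barrier continuous, and `barrierContinuity`
audits it as (i) every polygon a closed seam cycle, (ii) every seam shared
by at least two cells, (iii) the en face union of polygons covering the
periodic plane (grid sampling with a small diagonal nudge to resolve
points that land exactly on seam lines).

## Parameters and calibration

| parameter | default | meaning |
|---|---|---|
| `waitMax` | 9.6 hr | uniform waiting bound of rule 2 |
| `disappearance` | 2.4 hr | TJ disappearance during phase 1 |
| `dtMinutes` | 7.2 min | frame interval |
| `nx`, `ny` | 21 × 21 | periodic column lattice |
| `burnIn`, `duration` | 48 hr, 480 hr | discarded/measured intervals |
| `flattenRatio` | 0.25 | cell flattening (z only) |
| `init` | `"crystal"` | parity-ordered initialization |

The disappearance duration is the product of the 24-hr turnover time and
the 9.8% double-edged share: `calibrateDisappearance(24, 9.8)` returns the
exact 2.352 hr and the printed 2.4 hr, which the model uses.  At steady
state the two quantities are linked by renewal: the double-edged fraction
equals disappearance/period, so with a 2.4-hr disappearance an emergent
period near 24.5 hr yields the ~9.8–9.9% the default simulation produces.

**Residence time** is reported as the interval between successive
transition starts in a column — from a cell's promotion to its own
SG1 differentiation, both of which happen at transition starts under
rule 3.  Adding the fixed 2.4-hr disappearance to every interval would
make the 24-hr turnover time and the 9.8% share mutually inconsistent
with the renewal identity, so the start-to-start convention is the one the
calibration arithmetic itself implies.

**Initialization.**  Independent random entry times are *not* a valid
initial condition: age order must match height order on the interdigitated
lattice, and i.i.d. ages violate the 3-up/3-down packing almost surely.
The default `"crystal"` initialization assigns each parity class a
one-third-cycle age band (highest class oldest), the unique ordering
compatible with the untransformed lattice.  The `"iid"` option is kept for
exploration; it relaxes into a disordered, slow-turnover regime (~3.6%
double-edged) whose snapshots the extractor rejects as geometrically
unrealizable — a useful negative control.

**Lattice size.**  A fault-free interdigitated torus needs both side
lengths divisible by 3 (the height phase advances one third-stack per
step; along a closed loop of length $n$ the steps $+1$ and $-2$ must
cancel, which requires $3 \mid n$).  The default is therefore 21 × 21
(441 columns).  Other sizes run (the 3D packing is screw-periodic for any
size) but develop stacking-fault lines that depress the double-edged
share, and the flat en face honeycomb is only extracted for 3-divisible
tori.

## Measurement procedures

* **Polygon area** is the shoelace area of the en face projection of the
  ring's own outline.  For single-edged polygons bordered by an exterior
  polygon the reporting convention *includes* any region jointly claimed
  by both (`"include_overlap"`); the `"plain"` convention subtracts the
  grid-estimated intersection.  In meshes produced by this package the
  two coincide exactly, because neighbouring rings share their boundary
  vertices; the distinction matters only for independently traced
  outlines.
* **Polygon Z** is the mean of the vertex Z positions; **relative Z** is
  taken with respect to the mean of an octet (exterior + interior + their
  six single-edged neighbours) and therefore sums to zero per octet.
  The model reproduces the qualitative pattern: exterior positive,
  interior most negative, singles in between near zero.  Note the octet
  mean is dragged down by the interior polygon (a full stack lower), so
  the single-edged class lands slightly *above* zero here, while
  sub-micrometre tissue measurements put it slightly below; only the
  ordering is a model prediction.  An individual single-edged ring one
  parity step below the exiting cell can even lie above the exterior's
  mean Z — the class ordering is a statement about octet means, not
  about every polygon.
* **Windows.**  Double-edged percentages are counted in random square
  en face fields (default 20 windows of 15,376 µm²) by centroid
  membership, a pair counting once; the per-assay percentage pools that
  assay's windows and the SEM is taken across assays, mirroring the
  five-independent-assays design.

## The synthetic-microscopy generator

`makeNoisyHoneycomb()` emulates the *data structure* of en face
whole-mount TJ imaging: a polygon mesh with µm-scaled areas centred on
905.8 µm², a configurable double-edged rate (default 9.8%), and Gaussian
localization jitter applied per unique mesh vertex (shared corners move
together, as they are one physical point).  Planting draws from the
geometrically highest parity class, whose columns are never mutually
adjacent, so planted pairs are isolated by construction and rates above
one third are rejected.  It does **not** emulate pixel-level imaging:
no point-spread blur, no segmentation errors, no cell-size heterogeneity
beyond the three crystal classes, no curvature.  Passing recovery tests
therefore demonstrates that the measurement code is correct on meshes of
known truth — not that segmentation of real micrographs would be this
accurate.

## Numerical choices

* Event times are quantized to the 7.2-min frame; the zero-wait limit
  shows the expected dt-dependence (period = disappearance + one frame)
  and converges to the event-driven value as dt shrinks.
* Seam identity uses canonical coordinate keys rounded to 10⁻⁵ lattice
  units after minimal-image reduction on the torus.
* Entry times are made distinct at initialization; simultaneous
  transition starts in one frame share a timestamp but only adjacent ties
  would be ambiguous, and those cannot arise (adjacent columns are never
  simultaneously eligible).  Adjacent ties raise an error rather than
  being broken arbitrarily.
* Coverage is sampled on a 40 × 40 grid by default with an off-lattice
  offset and a four-direction nudge for points lying exactly on seams.

## Problem sizes used by the tests

The test suite runs reduced but structurally identical problems: 12 × 12
columns over 288 hr (two seeds) for the headline fraction/residence
checks, 9 × 9 over 144 hr for honeycomb invariants, and a 6 × 6 run
audited for barrier continuity at every 7.2-min frame over 24 hr.  The
acceptance script runs the full protocol (21 × 21, 48 + 480 hr, five
seeds).  All randomness flows from explicit seeds; every reported
statistic carries its n.

## Known limitations

* Basal supply is idealized: every column promotes an SG3 cell on demand;
  stem-cell kinetics, lineage structure and shedding are out of scope.
* No mechanics: cells are rigid polyhedra; no forces, rearrangements or
  shape variability, so the model cannot speak to mechanical perturbations.
* The crystal regularity is an idealization of locally ordered tissue;
  real honeycombs show size dispersion the synthetic generator only
  caricatures with vertex jitter.
* Absolute Z magnitudes scale with the unconstrained flattening ratio;
  only Z orderings and sign patterns are meaningful.
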