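---
title: "Tracing polysomes and quantifying ribosome heterogeneity from subtomogram poses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing polysomes and quantifying ribosome heterogeneity from subtomogram poses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PolysomeTracer)
```

## The problem

In cellular cryo-electron tomography, subtomogram averaging yields a
position and an orientation for every ribosome in a cell, but the mRNA
that strings ribosomes into polysomes is itself invisible at these
resolutions. Polysomes must therefore be *inferred* from the relative
poses of neighbouring ribosomes: if one ribosome's mRNA exit channel
sits a plausible mRNA-length away from another ribosome's mRNA entry
channel, the two are likely adjacent on one message. This package
implements that inference, the summary statistics used to compare
ribosome classes on the resulting chains (here, ribosomes carrying one
or two copies of the ribosomal protein bS20, or Trigger-Factor bound
and free ribosomes), a synthetic-scene generator that provides planted
ground truth for every stage, and a structural module for quantifying
a protein's binding interfaces in an atomic model.

## The tracing model

Two markers — the mRNA entry and exit sites on the small subunit — are
fixed as offsets $\mathbf{v}_{entry}, \mathbf{v}_{exit}$ (Å) from the
particle centre in the subtomogram-average frame. For a particle with
refined position $\mathbf{p}_i$ and ZYZ Euler angles
$(\phi_{rot}, \theta_{tilt}, \psi)$ building
$R_i = R_z(\phi)R_y(\theta)R_z(\psi)$, the marker maps to the tomogram
frame as

$$\mathbf{m}_i = \mathbf{p}_i + A_i\,\mathbf{v}, \qquad
  A_i = R_i^\top \text{ (default)} .$$

Tracing then applies four deterministic rules per tomogram (= cell):

1. **link**: for every particle $i$, find the nearest entry marker
   $j\neq i$ to $\mathbf{m}^{exit}_i$; register $i \to j$ if the
   distance is strictly below the tracing cut-off (250 Å = 25 nm);
2. **resolve**: if several particles share the same neighbour $j$,
   keep only the shortest incoming link;
3. **open circles**: with in- and out-degree at most 1 every component
   is a path or a simple cycle; each cycle loses its longest link;
4. **chain**: each remaining maximal path becomes one polysome,
   ordered from the particle with no incoming link.

All ties are broken towards the smaller particle ID, which makes the
pipeline a pure function of its input; ties have measure zero on real
coordinates. `tracePolysomes()` reports how many links each rule
removed, and `runPipeline()` writes those counts to a JSON-lines log
so the audit trail is machine-checkable.

### The rotation-direction convention

Refinement packages disagree on whether stored Euler angles rotate the
reference onto the particle or vice versa, and this is the single most
common source of silent error in subtomogram tooling. The package
therefore exposes the choice as `mapDirection` in `markerConfig()`:
`"inverse"` (default) maps markers with $R^\top$, matching the
convention in which stored angles align the particle to the reference;
`"forward"` uses $R$. `exportMarkers()` renders the marker cloud under
*both* conventions as CSV/STAR point clouds so the correct one can be
confirmed visually against a map before any tracing is trusted. The
synthetic generator and the tracer share one convention, so all
round-trip tests hold under either setting.

### Coordinates and units

All internal geometry is in Å with right-handed axes. STAR coordinates
are multiplied by the pixel size at load, and refined origin offsets
are subtracted when present — both the pixel-unit (`rlnOriginX`) and
the Ångström-unit (`rlnOriginXAngst`) dialects are honoured, so the
refined position is `coordinate × pixelSize − origin_Å`. Whether the
original analysis used shift-corrected or raw coordinates is not
recorded anywhere we could consult; shift-corrected is the default
here and `applyShifts = FALSE` restores the raw convention. Euler
angles are normalised at load to tilt ∈ [0°, 180°], rot/psi ∈
(−180°, 180°], using the identity
$R_y(-\theta) = R_z(180°)R_y(\theta)R_z(180°)$, which leaves the
rotation matrix bit-for-bit unchanged.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `entryOffset`, `exitOffset` | (55, 0, 0), (−55, 0, 0) | Å | marker sites in the reference frame, 110 Å (11 nm) apart |
| `traceCutoff` | 250 | Å | maximum exit→entry distance for tracing (25 nm) |
| `distanceCutoff` | 500 | Å | cut-off for the neighbour-distance (elongation-rate) analysis (50 nm) |
| `mapDirection` | inverse | — | rotation-direction convention |
| SASA `probe` | 1.4 | Å | water-probe radius |
| SASA `nPoints` | 960 | — | golden-spiral sphere samples per atom |
| contact `cutoff` | 4.0 | Å | heavy-atom contact distance |

The numeric marker offsets are user configuration — they depend on the
reference average used for alignment and are not derivable from the
particle table. The defaults place entry and exit on opposite sides of
the small subunit, roughly 11 nm apart, which is in the range of a 70S
ribosome's mRNA channel separation; any real study should set them
from its own average and verify with `exportMarkers()`.

## The neighbour-distance analysis

`neighbourDistances()` records, for every particle with a nearest
entry neighbour below 500 Å, the exit→entry distance annotated with
the class labels of the leading and trailing particle, stratified into
the four label pairs. By default these distances come from the
*pre-resolution* link set (each particle's single nearest neighbour):
the 50 nm cut-off is specified separately from the 25 nm tracing
cut-off, which indicates a neighbour-level rather than a chain-level
quantity; `resolved = TRUE` restricts to links that survive
shared-neighbour resolution and cycle opening, so both readings are
available.

`cellConfidenceBand()` turns per-cell normalised histograms into
empirical 5th/95th percentile bands across cells, with the point
estimate either the mean of per-cell curves (default) or the pooled
histogram — both modes exist because a published band of this kind can
be computed either way. With fewer than 3 cells the band degenerates
to the point estimate with a warning.

`compareStrata()` performs pairwise two-sample Kolmogorov–Smirnov
tests between strata with Holm correction. No particular test is
canonical for "no significant difference between inter-ribosome
distances"; KS was chosen because it is distribution-free and
sensitive to any distributional difference, not only location shifts,
and the choice is recorded in the output metadata. Its type-I error at
n = 500 per stratum is calibrated (≈0.05) in the acceptance suite.

Two reporting conventions are deliberately explicit because the
quantities are otherwise ambiguous:

* **SD convention** — per-cell and per-chain summaries use the
  population SD (divide by $n$) by default, with `sdType = "sample"`
  available; neither convention is universal and silent defaults are
  worse than either choice.
* **Composition mean** — the per-polysome class fraction is averaged
  unweighted across chains (each polysome counts once), and the
  ribosome-weighted mean is always reported alongside, since "average
  ratio per polysome" admits both readings.

## The synthetic generator

`simulateScene()` emulates the statistical structure the analysis
assumes: multiple cells, planted polysome chains, isolated monosomes,
i.i.d. Bernoulli/categorical labels, optional positional noise.
Defaults are the study-scale conditions: 28 cells, bS20 large-subunit
occupancy 0.67, Trigger-Factor bound fraction 0.88, polysome lengths
2 + Poisson(3) (mean 5), step distances N(70, 15²) Å truncated
positive, 6 polysomes and 30 monosomes per 5000×5000×1500 Å cell
(≈60 particles per cell, a deliberately desk-scale stand-in for the
hundreds visible in a real lamella — across-cell binomial scatter is
correspondingly larger than in the real data).

Polysome paths are bounded-turn 3-D random walks (≤60° per step —
a parameterised morphology choice, not a fit to any data). Member
orientations are *path-following*: each member's orientation is the
rotation taking the reference exit direction onto the local walk
direction, composed with ≤20° of uniform-axis jitter, and the member
is then positioned so its mapped entry marker lands **exactly** at the
drawn step distance from the predecessor's mapped exit marker. Two
further guarantees make planted recovery a geometric fact rather than
a tendency:

* within a chain, a candidate polysome is rejected unless every true
  link is *strictly* the nearest exit→entry pair (non-adjacent marker
  pairs must exceed the longest drawn step);
* monosomes and distinct polysomes keep a centre-to-centre clearance
  (default 600 Å) large enough that no cross-object marker pair can
  fall under the tracing cut-off.

Under these conditions the tracer provably returns exactly the planted
links: any residual spurious candidate is strictly longer than the
competing true link (removed by the shared-neighbour rule) or closes a
circle as its longest link (removed by cycle opening). The acceptance
suite verifies precision = recall = 1.0 over 100 seeds.

What the generator does **not** emulate: classification errors (labels
are exact, not a classifier model), missing particles, membrane or
cell-boundary effects, curvature of real polysome morphologies beyond
the bounded-turn walk, and localisation error beyond isotropic
Gaussian position noise. Passing tests therefore demonstrate
correctness of the *rules* and calibration of the *estimators*, not
robustness to picking or classification failure modes on real
tomograms.

`emitFixtureSuite()` writes a graded set of STAR fixtures with truth
JSON: a hand-checkable 3-particle chain, the 28-cell study mimic, an
exact shared-neighbour tie, a pair straddling the tracing cut-off by
±0.5 Å, and a symmetric ring whose naive linking closes into a cycle
so that cycle removal is *required* for correct output.

## The structural-interface module

`loadStructure()` parses mmCIF or PDB coordinates (via bio3d) into a
flat heavy-atom table: hydrogens, waters and common ions are dropped,
and alternate locations resolve to the highest occupancy (ties to the
alphabetically first altloc). `superposeRmsd()` is a standard
SVD-based Kabsch superposition with reflection correction;
`pairCommonResidues()` pairs C-alpha atoms by residue number over the
range modelled in both chains, which is the right pairing when one
copy of a protein has a disordered terminus. `sasa()` implements
Shrake–Rupley accessibility with a *deterministic* golden-section
spiral point set (n = 960 by default), so results are exactly
reproducible; the radii are a Bondi-style heavy-atom set (C 1.70,
N 1.55, O 1.52, S/P 1.80 Å, default 1.70 Å with a warning) printed in
every report, because buried-area numbers are only comparable when the
radii and probe are stated. `buriedArea()` computes
SASA(A) + SASA(B) − SASA(AB) with a per-partner-chain split, and
`contactResidues()`/`classifyBinders()` classify residues into
site-specific and shared binders given two site definitions. The
4.0 Å heavy-atom contact cut-off is configurable since no single value
is canonical; contact sets grow monotonically with the cut-off.

Applying the module to a deposited two-site model (e.g. a ribosome
carrying the same protein at two binding sites) requires the
coordinate file; `fetchStructure("9HC4")` retrieves it when a network
is available, `findDuplicateProteinChains()` locates the two copies
without assuming chain identifiers, and the copy with the shorter
modelled range (disordered N-terminus) is the large-subunit site.
Published buried areas carry method dependence (radii, probe, point
density, treatment of ions), so agreement should be judged at the
±15% level, and RMSD at roughly ±0.15 Å, when the depositing tool's
parameters are unknown.

## Numerical choices and degenerate inputs

* Distances are compared strictly (`< cutoff`); a pair exactly at the
  cut-off does not link.
* Nearest-neighbour search is the exact O(n²) scan per tomogram,
  vectorised; cells of a few hundred particles are far below the size
  at which an equivalence-preserving spatial index would matter.
* Empty tomograms, empty particle sets and label-free strata are
  returned empty, never errors; degenerate contingency tables skip the
  chi-square test with a notice; fewer than 3 cells degrade the
  confidence band with a warning.
* `breakCycles()` and `chainPolysomes()` verify their degree-bound
  preconditions and fail loudly on malformed graphs.
* Superposition with fewer than 3 atom pairs or collinear coordinates
  is refused as ill-conditioned rather than silently returned.

## Worked example

```{r example, eval = FALSE}
mk <- markerConfig(entryOffset = c(55, 0, 0), exitOffset = c(-55, 0, 0))
sc <- simulateScene(sceneParams(), seed = 1)
tr <- tracePolysomes(sc$particles, mk)
tr$counts
occupancyByCell(sc$particles, "occupancy", "2xbS20")[c("mean", "sd")]
compositionFractions(tr$chains, sc$particles, "occupancy",
                     "2xbS20")[c("mean", "sd")]
```

The acceptance script (`scripts/acceptance.R`) recomputes all headline
quantities from scratch — tracer-vs-brute-force agreement on 1000
random scenes, planted precision/recall over 100 seeds, the 28-cell
parameter recovery, KS calibration over 100 replicates, and the
closed-form accessibility checks — and writes them as JSON. Problem
sizes (1000 scenes of ≤10 particles, 28 cells of ≈60 particles, 100
replicates) are the package's chosen desk-scale study conditions.

## Known limitations

* The tracer assumes one mRNA per chain geometry; branched or densely
  packed configurations where a single entry is genuinely contested
  are resolved by the shortest-link rule, not by modelling the mRNA
  path.
* Chain polarity ("upstream/downstream") is defined purely
  geometrically: a link i → j means i's exit feeds j's entry and the
  chain start is the node with no incoming link. Biological 5'→3'
  naming of that polarity is a labelling question the geometry cannot
  decide.
* Buried areas depend on radii/probe/point-density conventions;
  cross-tool comparisons need the parameters printed in the report.
* The pure-R Shrake–Rupley implementation targets chain-versus-chain
  interfaces (thousands of atoms); whole-ribosome SASA should be
  restricted to an interface shell first (far atoms cancel exactly in
  the buried-area difference).
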