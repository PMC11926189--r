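# PolysomeTracer

Polysome tracing and ribosome-heterogeneity analysis from subtomogram
particle poses, in R.

In cellular cryo-electron tomography, subtomogram averaging gives every
ribosome in a cell a refined position and orientation, but the mRNA
that strings ribosomes into polysomes is invisible. Polysomes are
therefore inferred from relative poses: a marker at the mRNA **exit**
site of one ribosome that lies within a cut-off distance of the mRNA
**entry** site of a neighbour indicates adjacency on one message. This
package implements that inference as a tested pipeline and the
statistics used to ask whether structurally distinct ribosome classes
(e.g. ribosomes carrying one vs. two copies of protein bS20, or
Trigger-Factor bound vs. free) behave differently on polysomes.

## The method

For particle *i* with position **p**ᵢ and ZYZ Euler angles building
R = R_z(rot)·R_y(tilt)·R_z(psi), a reference-frame marker **v** maps to
the tomogram as **p**ᵢ + Rᵀ**v** (the direction convention is
configurable and can be validated visually with `exportMarkers()`).
Tracing applies four deterministic rules per cell:

1. link each exit site to its nearest entry site if closer than the
   tracing cut-off (250 Å = 25 nm);
2. when particles share a neighbour, keep only the shortest link;
3. open every closed circle by removing its longest link;
4. read the remaining maximal paths off as polysome chains.

On top of the chains: per-polysome class fractions, per-cell
occupancies, exit→entry distance distributions by class pair (at the
50 nm analysis cut-off) with 5–95% cell-to-cell confidence bands, and
pairwise Kolmogorov–Smirnov comparisons with Holm correction. A
synthetic-scene generator plants ground-truth polysomes so every stage
is testable, and a structural module quantifies dual binding sites in
atomic models (Kabsch RMSD, Shrake–Rupley SASA, buried interface
areas, contact-residue classification).

## Worked example

```r
library(PolysomeTracer)

mk <- markerConfig(entryOffset = c(55, 0, 0), exitOffset = c(-55, 0, 0))
sc <- simulateScene(sceneParams(), seed = 1)   # 28-cell study-scale mimic
tr <- tracePolysomes(sc$particles, mk)
tr$counts
#>      particles candidateLinks  removedShared  removedCycles         chains
#>           1688            689              8              1            168

tr$chains
#> PolysomeChainSet with 168 chains
#>   lengths: min 2 median 5 max 9 ; 848 linked particles

occupancyByCell(sc$particles, "occupancy", "2xbS20")[c("mean", "sd")]
#> $mean [1] 0.6532  $sd [1] 0.0652

compositionFractions(tr$chains, sc$particles, "occupancy",
                     "2xbS20")[c("mean", "sd")]
#> $mean [1] 0.6640  $sd [1] 0.2211
```

The scene was generated with a true 2×bS20 occupancy of 0.67: the
per-cell occupancy estimate (0.653 ± 0.065 across 28 cells) and the
mean per-polysome 2×bS20 fraction (0.664 ± 0.221 across 168 chains)
both recover it, and the tracer's audit counts show how many candidate
links each rule removed. `writeParticles()` exports the chains back
into an annotated STAR file; `runPipeline()` (or the CLI in
`inst/scripts/polytrace.R`, with subcommands `simulate`, `trace`,
`stats`, `interface`, `all`) wraps the whole run into a reproducible
output directory with a machine-readable log.

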