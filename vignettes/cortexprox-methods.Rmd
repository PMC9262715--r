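---
title: "Models and methods behind cortexprox"
author: "cortexprox authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cortexprox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cortexprox` analyses per-cell tables from imaging-based spatial
transcriptomics of the cortex: centroid position (µm), soma radius,
normalized cortical depth, and a three-level cell-type label
(class → subclass → cluster). This vignette explains the statistical
models, the synthetic-tissue generator used to validate them, the
parameters that matter, and the design choices made where the design was
genuinely open.

## The data model

A section is a flat rectangle; depth is `y / section_height`, 0 at the
pial surface, with the six laminar compartments L1 | L2/3 | L4 | L5 |
L6 | WM delimited by five relative boundaries (defaults 0.09, 0.35,
0.47, 0.70, 0.88). Layer assignment uses half-open intervals
`[b_k, b_{k+1})`: a depth exactly on a boundary belongs to the deeper
layer (a stated tie rule, since published laminar boundaries are always
approximate), and any depth at or beyond the last boundary is white
matter. All distances are Euclidean in 2-D — sections are treated as
planar, as in per-slice analyses of real data.

The packaged taxonomy has 125 clusters (29 excitatory, 39 inhibitory, 57
non-neuronal) in the canonical cortical subclasses; glia are
ASC ∪ OGC ∪ OPC ∪ MGC, so endothelial and mural cells count as
non-neuronal but never as glia in the glia:neuron ratio.

## The synthetic cortical section

The generator exists so that every analysis stage can be exercised
against known ground truth. One call produces a cell table and a sparse
expression matrix:

1. **Counts and labels.** The number of cells is Poisson with mean
   density × area (human default 2,000 cells/mm²; mouse 6,000, three
   times denser). Each cell draws a cluster from the configured
   composition.
2. **Depth.** Each cluster has a truncated-Gaussian depth profile on
   [0, 1] (mean, sd configured per cluster; e.g. the L4/5 IT band is
   deliberately dense and thin, sd 0.03, while PVALB and SST are broad,
   sd 0.15). Depths are drawn by inverse-CDF once per cell.
3. **Hard-core placement.** Cells are placed by dart throwing with a
   minimum centroid separation (human 8 µm). On a collision only `x` is
   re-sampled and the drawn depth is kept, so the realized depth
   marginal of every cluster is *exactly* its configured truncated
   normal — re-drawing depth would bias cells away from dense
   compartments. The rejection budget is 100 attempts per cell; an
   infeasible density/hard-core combination fails with an explicit
   error. The mouse default hard-core is 5 µm: at three-fold density the
   human 8 µm floor would push laminar density peaks past the hard-disk
   jamming limit, and mouse packing is genuinely tighter.
4. **Injections** (the interaction ground truth):
   - *Satellites*: a configured fraction of a partner subclass is
     relocated to exact contact distance `r_i + r_j + gap` (gap 0.5 µm)
     from focal cells, `partners_per_focal` at a time for multiway
     structure. Human defaults inject microglia satellites on IT neurons
     with a fraction decreasing from L2/3 IT (0.27 of all microglia) to
     L6 IT (0.012), oligodendrocyte/OPC triplets on L2/3 and L5 IT
     neurons, and intra-subclass SST (0.40) and PVALB (0.35) pairs. The
     intra-subclass fractions are deliberately large: for a subclass at
     ~3% abundance, the one-sided "self < other" nearest-neighbor
     rank-sum test can only reject when most cells of the subclass sit
     in an injected pair (each pair gives both members a ~10.5 µm self
     neighbor, while the nearest *other* cell is typically ~15 µm away);
     a power calculation, not a fit to data.
   - *Vessels*: endothelial/mural cells are relocated onto
     persistent-direction self-avoiding chains at contact spacing
     (8.5 µm steps), confined to the cortical ribbon; perivascular glia
     (human default: 2 microglia and 2 oligodendrocytes per vessel) are
     placed at contact distance from random chain members. Mouse
     sections carry vessels but recruit no glia.
   - Satellites and vessel members are exempt from the hard-core rule
     (flagged in the output `placement` column); only free cells are
     subject to it, and the packaged tests verify this with an all-pairs
     oracle.
5. **Expression.** Counts are negative binomial (baseline mean 0.4 per
   gene, size 3) with a per-cell lognormal library factor (σ = 0.3, so
   normalization is non-trivial), marker genes multiplied by 25 in their
   clusters, GAD2/SLC32A1 silenced in all OPCs, GAD1 expressed from the
   marker model in a latent Bernoulli(0.5) OPC subpopulation, and an
   A2M→LRP1 boost (×3) in contacting microglia→IT pairs.

### White-matter compensation

The headline composition numbers (26% excitatory / 11% inhibitory / 63%
non-neuronal; glia:neuron 1.4; E:I 26/11; IT 93% of excitatory with
splits 46/18/19/13/4; inhibitory splits 13/26/30/31) are white-matter
*excluded* quantities. Because some clusters (WM oligodendrocytes, deep
astrocytes, L6b) put part of their depth mass beyond the WM boundary,
`defaultHumanConfig()` divides each cluster's target share by its
closed-form non-WM retention under the truncated normal and
renormalizes; the WM-excluded expectation of the generated composition
then equals the targets exactly. The WM depth band is kept
oligodendrocyte-enriched but below hard-core jamming density (WM cluster
means 0.90–0.96, sd 0.08).

Mouse shares are only constrained by published ratios (glia:neuron
0.28 = 1.4/5, E:I 6.9 = 2.3 × 3, non-IT 29% of excitatory, density ×3);
the remaining splits (e.g. the PVALB-shifted inhibitory split 8/40/35/17
and the within-glia split) are free parameters chosen once for
plausibility and documented here as such.

## Composition and laminar statistics

`cellComposition()` counts labels over a chosen denominator population
(all cells, neurons, excitatory, inhibitory, or IT) after removing WM
cells (the convention the headline numbers use; cells with depth > 1 and
no layer label are treated as WM with a warning). `compareSpecies()`
reports per-label human/mouse proportion ratios and the ratio-of-ratios
for G:N and E:I, with zero-denominator ratios reported as missing, never
infinite.

`depthProfiles()` bins depth uniformly (default 50 bins); per-cluster
densities are normalized to unit area, clusters under `minCells = 20`
are flagged and excluded from profiles but still counted in the E:I
curve. The E:I z-score standardizes the log2 E:I curve across bins
(mean 0, sd 1 over finite bins): the log stabilizes a ratio whose
denominator is small in L1, and across-bin standardization is used
because the alternative (across-species per bin) needs paired sections;
bins with no inhibitory cells propagate as missing.

## The proximity machinery

**Contact rule.** Centroid mode links cells at distance
≤ s·(r_i + r_j), s = 1.1 by default — soma contact "or proximity",
allowing a ~10% gap relative to touching somata. Boundary mode links
cells whose somata dilated by τ = 1 µm overlap (circular somata:
d ≤ r_i + r_j + 2τ). Both constants are exposed and recorded in the
graph object so every edge is re-checkable. Neighbor search uses grid
bucketing with a 9-offset join; the tests pin its equality with the
all-pairs rule.

**Density-preserving permutation null.** Labels — more precisely,
(class, subclass, cluster, soma radius) units — are shuffled among the
cells of each rectangular spatial bin, positions fixed. Per-bin per-type
counts are exactly preserved, so each type's coarse spatial density
survives while neighbor identity is destroyed. Two design points,
both driven by calibration analysis on injection-free synthetic
sections:

- *Bins are anisotropic*: 100 µm laterally × 25 µm in depth. Cortical
  tissue is statistically homogeneous along the layer but strongly
  graded across depth (a dense thin band like L4/5 IT varies severalfold
  within 100 µm); square 100 µm bins leave same-band cell pairs
  genuinely enriched relative to the within-bin shuffle and inflate the
  false-positive rate several-fold. 25 µm depth bins preserve the
  gradient; 100 µm lateral extent keeps enough cells per bin
  (~5–10 at human densities) for the shuffle to have support.
- *Edges travel with radii*: the contact threshold depends on soma
  radii, and radii are label-correlated (excitatory somata 6 µm, glia
  4.5 µm). Relabeling cells while freezing the edge set therefore leaves
  large-soma same-type pairs with structurally more edges than any
  relabeling can reproduce — a false-positive machine. Each permutation
  instead re-derives edges from precomputed candidate pairs under the
  permuted radii, which is the exact meaning of "re-placing types at
  fixed positions". With both choices the pairwise test is calibrated
  (the packaged acceptance suite checks the false-positive rate at
  α = 0.05 and 0.01 over 20 injection-free replicate sections).

**Pairwise enrichment** reports, per unordered label pair, the observed
edge count, permutation null mean/sd, fold change, upper-tailed normal
Z p-value (as is conventional for this statistic), the empirical
permutation p for auditability, and BH FDR over all pairs of the
analysis run (human and mouse sections are corrected separately). Pairs
with a degenerate null (sd 0) are flagged rather than assigned p = 0;
pairs with null mean < 5 are flagged low-power.

**Nearest-neighbor self/other test.** Per cell, the distance to the
nearest same-label and nearest different-label cell (computed per label
for "self", jointly for "other"; identical to brute force, verified in
tests); per label a one-sided Wilcoxon rank-sum tests self < other, BH
across labels. Note the test is conservative for rare labels — under
complete spatial randomness a rare type's self-neighbor is far by
construction — which is why detectable intra-subclass pairing requires
the pervasive pair structure described above.

## Interaction analyses

**Vessels** are connected components (≥ 3 cells — a structure, not a
lone cell) of the contact graph restricted to endothelial + mural
cells; adjacency counts per glial subclass are cells contacting any
member, summarized as mean ± sd across vessels.

**Multiway contacts** count, per k, focal neurons with ≥ k distinct
oligodendrocyte/OPC contact partners, compared against the same
permutation null (BH across k).

**GAD1⁺ OPCs** are OPCs with ≥ 1 GAD1 transcript (imaging counts are
near-binary for low expressors); sensitivity at thresholds 1–3 is
reported alongside, and GAD2/SLC32A1 absence is verified when the panel
contains them.

**Depth-dependent contact** reports, per ordered focal group (IT
subclasses superficial→deep, plus inhibitory), the observed/expected
microglia-contact ratio with its permutation distribution and a Spearman
trend of median ratio versus depth order. Null counts of zero are
floored at 0.5 for the ratio distribution only (the test statistics use
the raw moments).

**Ligand–receptor enrichment** scores a directed pair over contacting
sender→receiver cell pairs as the mean of n_L(sender)·n_R(receiver),
n = counts normalized to 1,000 per cell. Cells under a QC floor of 15
total counts are excluded — the normalized expression of near-empty
cells is numerically unstable and dominates a mean-of-products score.
The null draws one replacement cell per *distinct* observed cell, from
the depth bin (1/50 of the depth range) of the cell it replaces, and
reuses it with the observed multiplicity, so the null score has the
observed score's effective sample size; by default replacements come
from all sender/receiver-type cells regardless of contact status (an
exchangeability null that is calibrated by construction), with
`nullPool = "noncontacting"` available for a direct
contacting-vs-non-interacting contrast. Because the score is
heavy-tailed, the BH FDR uses the empirical permutation p; the
upper-tailed Z is reported as a descriptive effect size. Orientations
(e.g. microglia→neuron vs neuron→microglia) are separate analyses.

## Reproducibility and problem sizes

Every stochastic operation takes an explicit seed; the pipeline spawns
per-stage seeds from one global seed by stage-name hashing, and reruns
are byte-identical. The packaged validation uses a ~50,000-cell human
section for composition and GAD1 recovery, ~25,000/30,000-cell sections
for cross-species ratios, twenty ~5,000-cell injection-free sections for
null calibration, and ~20,000/15,000-cell human/mouse sections with 500
permutations for the directional interaction contrasts — sizes chosen so
binomial sampling error sits well inside the tolerances being checked.

## What the generator does and does not emulate

It emulates laminar layer structure, the published composition and
ratio targets, hard-core soma exclusion, satellite pairing, vessel-like
chains with perivascular recruitment, a GAD1⁺ OPC subpopulation, and
contact-conditioned ligand–receptor structure. It does **not** emulate
cortical curvature (depth is literally y/height), segmentation errors or
doublets, spot-level transcript positions, detection-efficiency
differences between gene panels, spatial expression gradients within a
cell type, or cross-section batch effects. Passing tests on synthetic
tissue therefore demonstrate correctness and calibration of the
statistics under a faithful but idealized tissue model — not robustness
to segmentation artifacts or real biological confounders.

## Known limitations

- The permutation null conditions on the realized geometry; it tests
  label–geometry association, not the point process itself.
- The normal-approximation Z is reported for contact counts because the
  statistic is a sum of many weakly dependent indicators; for the
  heavy-tailed ligand–receptor score inference relies on the empirical
  permutation p instead, whose resolution is 1/(B+1).
- Boundary-mode contact currently uses the circular-soma geometry;
  measured nucleus polygons are exported (GeoJSON) but not yet consumed
  by the graph builder.
- Cross-species comparisons assume subclass-level label correspondence.
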