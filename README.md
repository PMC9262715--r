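# cortexprox

Cell composition, laminar organization and soma-proximity statistics for
spatially resolved single-cell atlases of the cerebral cortex.

Imaging-based spatial transcriptomics (MERFISH and kin) yields per-cell
tables — centroid coordinates, soma size, cortical depth and a
transcriptomic cell-type label — for hundreds of thousands of cells per
tissue section. `cortexprox` implements the statistical layer that turns
such tables into biology:

- **Composition** — per-class/subclass/cluster proportions with the two
  headline ratios of cortical cytoarchitecture, glia:neuron
  (G:N = (ASC+OGC+OPC+MGC) / (EXC+INH)) and excitatory:inhibitory (E:I),
  plus human-vs-mouse ratio-of-ratio comparisons.
- **Laminar organization** — per-cluster cortical-depth densities,
  layer assignment, and the depth-resolved E:I curve with its across-bin
  z-score.
- **Soma contact / proximity** — a contact graph (edge when centroid
  distance ≤ s·(r_i + r_j), default s = 1.1, or when dilated soma
  boundaries overlap), tested against a *density-preserving label
  permutation null*: cell-type labels (carrying their soma radii) are
  shuffled within small spatial bins so each type's laminar density is
  preserved while neighbor identity is destroyed. Pairwise enrichment is
  reported as fold change = observed/expected with an upper-tailed Z-test
  and BH FDR; a one-sided Wilcoxon rank-sum test compares
  nearest-neighbor distances "to self" vs "to other" per subclass.
- **Higher-order and molecular interactions** — blood-vessel detection
  (connected components of the endothelial/mural contact subgraph) with
  per-vessel glial adjacency; multiway neuron–oligodendrocyte/OPC contact
  statistics; GAD1⁺ OPC classification; depth-dependent microglia–IT
  contact trends; and contact-conditioned ligand–receptor enrichment
  (score = mean over contacting sender→receiver pairs of
  n_L(sender)·n_R(receiver) on library-size-normalized expression,
  against depth-matched random re-pairings).
- **Synthetic tissue generator** — a fully parameterized cortical-section
  simulator (hard-core point process with laminar truncated-Gaussian
  depth profiles, satellite-cell and vessel-chain injections,
  negative-binomial expression with marker structure) whose defaults
  encode the published human/mouse temporal-cortex composition: 26%
  excitatory, 11% inhibitory, 63% non-neuronal cells, G:N = 1.4 (5× the
  mouse value), E:I = 2.3 (3× lower than mouse), IT neurons ~93% of
  excitatory, and ~50% GAD1⁺ OPCs. Every analysis stage can therefore be
  validated against known ground truth.

## Worked example

Generate a ~10,000-cell human-like section and run two analysis stages:

```r
library(cortexprox)

cfg <- resizeSection(defaultHumanConfig(seed = 1), 2000, 2500)  # um
tis <- generateTissue(cfg)

cellComposition(tis$cells, "class")
#> CompositionResult: level class / denominator all_cells (WM excluded)
#>   n = 9196 ; glia:neuron = 1.382 ; E:I = 2.338
#>          label count proportion
#> 1 non-neuronal  5755  0.6258156
#> 2   excitatory  2410  0.2620705
#> 3   inhibitory  1031  0.1121140

g   <- buildContactGraph(tis$cells)           # 4,948 edges over 9,937 cells
sch <- permutationScheme(nPermutations = 200, seed = 1)
enr <- pairwiseEnrichment(tis$cells, g, sch)
subset(enr, label_a == "L2/3 IT" & label_b == "MGC")
#>  label_a label_b observed null_mean fold_change        z          fdr
#>  L2/3 IT     MGC      211    116.06    1.818025 9.186769 3.279033e-19

gad1OpcFraction(tis$cells, tis$expression)$fraction
#> [1] 0.483
```

Read: the WM-excluded composition recovers the configured 26/11/63 split
and G:N ≈ 1.4 up to sampling noise; microglia (MGC) contact L2/3 IT
neurons 1.8× more often than the density-preserving null expects — the
satellite-microglia structure injected by the generator — at an FDR of
3×10⁻¹⁹; and 48% of OPCs carry at least one GAD1 transcript.

`runDemo("both", outDir = "demo")` runs the full pipeline (composition,
laminar, enrichment, NN test, vessels, multiway, depth-contact,
ligand–receptor) on paired human/mouse sections and writes one TSV per
table plus a manifest; reruns with the same seed are byte-identical.

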