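# barcodegap

OTU delimitation from DNA barcodes by automatic barcode-gap discovery — and
tools to quantify how much the answer depends on the alignment algorithm and
the distance correction you chose upstream.

## The problem

DNA-barcoding studies (for example ITS barcoding of fungal culture
collections) cluster sequences into operational taxonomic units (OTUs) by
exploiting the *barcode gap*: pairwise genetic distances within a species
are small, distances between species are large, and the empty interval in
between is a natural delimitation threshold. In practice the distances that
feed this decision are themselves products of two earlier choices — which
multiple-sequence-alignment program produced the alignment (Clustal Omega,
MAFFT, MUSCLE and Kalign can differ by hundreds of columns on the same
ITS barcodes) and which evolutionary distance correction was applied. OTU
counts reported by different pipelines are therefore not automatically
comparable. This package implements the full delimitation pipeline so that
the sensitivity of the OTU count to those choices can be measured directly,
on real alignments or on simulated data with known truth.

## What it computes

* **Alignment statistics** — alignment length, constant / parsimony-
  uninformative / parsimony-informative / all-missing site counts under the
  gaps-as-missing convention, and the number of distinct degapped
  sequences.
* **Pairwise distances under pairwise deletion** — the observed proportion
  of differences *p*; Kimura's two-parameter correction
  d = −½ ln[(1 − 2P − Q)√(1 − 2Q)] from transition (P) and transversion (Q)
  proportions; the Tamura–Nei (TN93) correction with unequal base
  frequencies and distinct purine/pyrimidine transition rates; and a
  closed-form pairwise GTR estimator
  d = −tr(Π log(Π⁻¹F̂)) from the symmetrised divergence matrix F̂. All
  support gamma rate-heterogeneity (shape α) and invariable-sites (I)
  adjustments; saturated pairs are flagged undefined, never silently
  zeroed.
* **Barcode-gap discovery** — ranked-distance gap detection given a prior
  intraspecific divergence P and relative gap width X, single-linkage
  partitioning at the gap midpoint, recursive within-group re-partitioning
  to a fixed point, and sweeps over a geometric grid of priors.
* **Tree diagnostics** — neighbor-joining trees, minimum-evolution score,
  Fitch parsimony tree length with consistency and retention indices
  (CI = M/S, RI = (G−S)/(G−M)), and the g1 skewness of tree lengths over
  uniform random topologies (negative g1 = phylogenetic signal).
* **Simulation with known truth** — a seeded two-scale star-phylogeny
  generator of ITS-like barcodes (HKY substitutions, explicit indel
  process, exact true alignment) so every stage of the pipeline can be
  validated against generating truth.

## Worked example

```r
library(barcodegap)

# 30 barcodes in 5 species: within-species p-distance 0.01, between 0.2
ds <- simulateBarcodes(simulationSpec(5, 6, 600, 0.01, 0.2, seed = 1))
ds
#> SimulatedBarcodes
#> SimulationSpec: 5 species, 30 sequences of 600 nt, intra 0.01 / inter 0.2, kappa 2, indel 0.02, seed 1
#>   alignment: 30 x 714; true partition: 5 species

gd <- geneticDistances(ds@alignment, "K2P")
scan <- detectBarcodeGap(gd, prior = 0.05)
sprintf("gap at rank %d: threshold %.4f", scan@gapIndex, scan@threshold)
#> "gap at rank 75: threshold 0.1158"

abgdRecursive(gd, prior = 0.05)
#> OtuPartition (recursive): 30 sequences in 5 groups

priorSweep(gd, 0.005, 0.3, steps = 5)
#>        prior n_initial n_recursive
#> 1 0.00500000        15          15
#> 2 0.01391579         5           5
#> 3 0.03872983         5           5
#> 4 0.10779123         5           5
#> 5 0.30000000         1           1
```

The 75 within-species distances end at rank 75, the detected gap's midpoint
0.116 sits inside the empty interval between the two divergence scales, and
partitioning there recovers the 5 generating species exactly. The sweep
shows the characteristic behaviour of gap-based delimitation: over-splitting
at priors below the intraspecific scale, a stable plateau at the true
species count, and collapse to a single OTU once the prior exceeds every
observed distance.

To compare several alignments and corrections in one call, use
`runComparison(alignments, models)`; a thin command-line front end over the
same functions is provided in `inst/scripts/barcodegap.R`.

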