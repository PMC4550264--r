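---
title: "Barcode-gap OTU delimitation: models, parameters and design choices"
author: "barcodegap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode-gap OTU delimitation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters and the choices made
where the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The delimitation model

The barcode-gap principle assumes that pairwise genetic distances among
conspecific sequences are drawn from a low-divergence distribution, that
distances between distinct species are drawn from a clearly higher one, and
that the two distributions do not overlap — leaving an empty interval, the
*barcode gap*, that can serve as a clustering threshold. The assumption is
strong: it fails for recent radiations, for markers with heterogeneous
rates across lineages, and whenever incomplete lineage sorting or
introgression blurs the scales. The package treats the principle as an
operational definition, not a biological truth, which is precisely why the
sensitivity analysis it supports (same barcodes, different alignments and
corrections, different OTU counts) is informative.

### Gap detection

Given a distance matrix, the defined distances are ranked ascending as
$d_{(1)} \le \dots \le d_{(N)}$ with consecutive gaps
$g_i = d_{(i+1)} - d_{(i)}$. The local gap scale at rank $i$ is the mean of
the up-to-$w$ gaps preceding $i$ (at least one, so rank 1 is never a
candidate), with window $w = \max(10, \lceil 0.01 N \rceil)$ by default.
The detected gap is the **first** rank whose gap ends at or above the prior
intraspecific divergence $P$ (so gaps lying entirely inside the assumed
intraspecific range are never selected) and exceeds $X$ times the local
scale. The partition threshold is the gap midpoint
$(d_{(i)} + d_{(i+1)})/2$.

Two points in this criterion were open design territory. First, the
published descriptions of automatic barcode-gap discovery state the
principle and its prior/relative-width parameters but not the exact
gap-significance statistic; the window-mean local scale and
first-qualifying-gap rule used here are this package's concretisation, and
both the window and $X$ are arguments precisely so the criterion can be
calibrated against a reference tool when reference data are available.
Second, the prior condition is applied to the *upper* edge of the gap
($d_{(i+1)} \ge P$): a genuine barcode gap typically *spans* the prior
(intraspecific distances below it, interspecific above), so conditioning on
the lower edge would reject exactly the gaps the method exists to find,
while conditioning on the upper edge makes the prior what its name says —
an upper bound on within-species divergence below which no gap is sought.
A prior above the gap's upper edge masks it, which is what produces the
characteristic collapse to a single OTU at large priors in prior sweeps.

### Partitioning and recursion

Partitioning at a threshold $t$ is single linkage: connected components of
the graph with an edge wherever a distance is defined and $< t$. Strict
inequality is deterministic here because thresholds are gap midpoints, so
no tie can straddle them. Undefined entries (see below) contribute no edge.

The *initial* partition is one pass of detection plus partitioning (one
group when no gap qualifies). The *recursive* partition re-runs the scan
inside every group of at least 3 sequences with the same prior and $X$,
repeating until nothing splits. Groups smaller than 3 offer fewer than
3 pairwise distances — structurally too few to estimate a gap — and are
never split. Recursion only ever subdivides, so the recursive partition is
a refinement of the initial one by construction (and by test).

### Prior sweeps

`priorSweep()` evaluates both partitions over a geometric grid
$P_k = P_{\min}(P_{\max}/P_{\min})^{k/(s-1)}$, by default 10 steps from
0.001 to 0.12 (consecutive ratio ≈ 1.70), the range conventionally scanned
for ITS barcodes. On clean two-scale data the counts over-split below the
intraspecific scale, plateau at the true species count, and collapse to one
group once the prior exceeds every distance.

## Distance corrections

All four corrections share one counting pass per sequence pair under
**pairwise deletion**: only sites where both sequences carry a determinate
A/C/G/T state are compared; `-`, `?`, `N` and IUPAC ambiguity codes are
missing. Complete deletion would be the alternative, but on indel-rich ITS
alignments it discards most columns, and per-pair counting matches the
default behaviour of the standard distance software in this field. For the
same reason TN93 base frequencies are estimated per pair from the pair's
shared sites by default (`freqMode = "global"` switches to alignment-wide
frequencies).

* **p-distance** — observed proportion of differing sites.
* **K2P** — $d = -\tfrac12\ln[(1-2P-Q)\sqrt{1-2Q}]$ with $P$ and $Q$ the
  transition and transversion proportions; equal base frequencies assumed.
* **TN93** — distinguishes A↔G and C↔T transition proportions $p_1, p_2$
  with unequal base frequencies:
  $d = -k_1\ln w_1 - k_2\ln w_2 - k_3\ln w_3$ with
  $k_1 = 2\pi_A\pi_G/\pi_R$, $k_2 = 2\pi_T\pi_C/\pi_Y$,
  $k_3 = 2(\pi_R\pi_Y - \pi_A\pi_G\pi_Y/\pi_R - \pi_T\pi_C\pi_R/\pi_Y)$,
  $w_1 = 1 - p_1/k_1 - q/(2\pi_R)$, $w_2 = 1 - p_2/k_2 - q/(2\pi_Y)$,
  $w_3 = 1 - q/(2\pi_R\pi_Y)$. At equal frequencies it reduces exactly to
  K2P (asserted by test).
* **GTR** — no closed form exists in terms of a few proportions, so the
  standard tree-free pairwise estimator is used: symmetrise the divergence
  matrix $\hat F = (F + F^\top)/2$, set $\Pi$ to the diagonal of its
  marginals, and $d = -\mathrm{tr}[\Pi \log(\Pi^{-1}\hat F)]$, the matrix
  logarithm taken by eigendecomposition of the similar symmetric matrix
  $\Pi^{-1/2}\hat F\,\Pi^{-1/2}$. Under equal-rate evolution this reduces
  analytically to the Jukes–Cantor formula, which the tests exploit as a
  simulation oracle.

**Rate heterogeneity.** A gamma shape $\alpha$ replaces each $\ln x$ with
$\alpha(1 - x^{-1/\alpha})$ (K2P additionally has its traditional
$\tfrac{\alpha}{2}[(1-2P-Q)^{-1/\alpha} + \tfrac12(1-2Q)^{-1/\alpha} -
\tfrac32]$ form), restoring the plain logarithm as $\alpha \to \infty$
(tested at $\alpha = 10^6$ against tolerance $10^{-6}$). A proportion of
invariable sites $I$ rescales the observed proportions by $1/(1-I)$ and the
result by $(1-I)$; for GTR the off-diagonal divergence mass is rescaled
with the marginal composition held fixed. Both parameters are
**user-supplied** (for example from an external model-selection run); the
package never estimates them, and default runs use neither.

**Saturation policy.** Whenever a logarithm argument or an eigenvalue is
non-positive the pair is *flagged undefined* (`NA` plus a `FALSE` mask
entry) rather than raising an error or returning $\infty$: one saturated
pair must not abort a 290-sequence analysis. Gap discovery simply excludes
undefined pairs from the ranking; neighbor joining, which needs every
entry, refuses incomplete matrices explicitly.

## Tree diagnostics

Neighbor joining uses the standard Saitou–Nei/Studier–Keppler
agglomeration; negative branch-length estimates are clamped to zero with
the count recorded, the common convention so that the minimum-evolution
score (the branch-length sum) stays non-negative. Fitch tree length, the
per-site minimum $m_i$ (distinct determinate states − 1) and maximum $g_i$
(determinate taxa − modal state count) give CI = $M/S$ and
RI = $(G-S)/(G-M)$ (defined as 1 when $G = M$; CI defined as 1 when
$S = 0$). CI/RI are computed over **all** sites by default, with
`informativeOnly = TRUE` available because published tables do not always
state which convention was used. The g1 statistic samples unrooted binary
topologies **uniformly** by random sequential addition (each of the
$(2k-5)!!$ topologies equally probable — verified empirically for 4 taxa)
and reports the skewness $m_3/m_2^{3/2}$ of the Fitch length distribution;
10,000 trees by default, fewer in the tests where only the sign and
magnitude matter.

These tree statistics are diagnostics, not delimitation inputs: tree
length, CI, RI and ME depend on the specific topology produced by a given
NJ implementation on a given distance matrix, so cross-software equality is
not promised — the properties that are promised (exact recovery of additive
matrices, Fitch equal to brute-force minima, invariance under re-rooting)
are asserted by the test suite.

## The simulator

`simulateBarcodes()` generates barcodes on a two-level star phylogeny: a
root sequence, species ancestors at calibrated distance, and tips radiating
within each species. Star trees were chosen over birth–death trees
deliberately: they give direct, analytically transparent control of exactly
the two divergence scales the barcode-gap principle assumes, which is what
makes generator-truth recovery a meaningful test. Substitutions follow an
HKY process (transition/transversion ratio `kappa`, composition
`baseFreqs`); branch lengths are calibrated by numerically inverting the
expected-p curve so the *realised* mean within- and between-species
p-distances hit `intraD` and `interD` despite multiple hits, and the
generator self-checks both to within 25% at `seqLen` ≥ 500.

Indels are applied after substitution with exact bookkeeping (the returned
alignment *is* the true homology; degapping recovers the raw sequences).
Events hit species-level branches with per-site probability `indelRate`,
and tip branches at `indelRate` scaled by relative branch length — indels
accumulate with divergence, and unscaled tip-level insertion would inflate
the alignment with hundreds of single-tip columns no real aligner would
produce. Event lengths are geometric with mean 3; insertions open a private
column block (gap in all other sequences).

`studyEmulationPreset()` fixes the scale of a realistic culture-collection
ITS campaign: 290 sequences in 75 species (sizes drawn once with an
internal seed, so they are part of the preset, not the realisation), raw
length 550 nt, `intraD` 0.012 and `interD` 0.15 — intraspecific K2P
divergence of order 0.007–0.018 with interspecific divergence an order of
magnitude larger, the regime reported for fungal ITS barcodes — with
`kappa` 2 and `indelRate` 0.02, which yields aligned lengths around
2,000 columns from 550 nt of sequence.

What the simulator does **not** emulate: secondary-structure-aware ITS
evolution, rate variation among lineages, chimeric or paralogous copies,
and — most importantly — the alignment-program-specific errors that real
aligners make on degapped sequences. Passing generator-truth tests
therefore shows the pipeline is internally correct, not that any particular
aligner's output is trustworthy; quantifying the latter on real data is
what `runComparison()` is for.

## Numerical and degenerate-input choices

* Bin assignment in `distanceHistogram()` rounds $v/w$ to 9 decimals before
  flooring so values on a bin edge are not displaced by floating-point
  representation.
* Partition labels are renumbered by first appearance in the matrix's id
  order, making partitions invariant (up to that canonical labelling) under
  input permutation — asserted by test.
* `GapScan` validity enforces that a detected threshold lies strictly
  inside its gap and that the gap ends at or above the prior.
* Distance matrices imported from PHYLIP files re-symmetrise as
  $(D + D^\top)/2$ and flag `NA` entries undefined.
* Alignments with fewer than 2 determinate characters in a column count
  that column as *all-missing*, not constant; the four site classes always
  partition the alignment length (asserted in `siteSummary()` itself).

## Problem sizes used by the tests and the acceptance script

The test suite validates the distance closed forms against an independent
implementation on hundreds-of-site pairs, Fitch against brute force on all
$4^4$ four-taxon patterns, NJ on additive 6-taxon matrices, and the
delimitation pipeline on simulated datasets of 12–30 sequences plus the
full 290-sequence preset; g1 uses 300–600 random topologies where only sign
and approximate magnitude are at stake. `scripts/acceptance.R` runs the
whole pipeline on the 290-sequence preset (three distance models, a
10-point prior sweep) and tree diagnostics on a 60-sequence subsample with
500 topologies. These sizes keep a full run in the tens of seconds while
leaving every quantity at the scale the methods are designed for.

## Known limitations

* The gap-significance criterion is a documented concretisation; other
  implementations' exact OTU counts may differ at priors near the edges of
  the gap, which is why the window and $X$ are tunable.
* The GTR estimator is the standard pairwise closed form; distance software
  that estimates GTR distances differently (for example by ML on a fixed
  topology) will not agree to the last digit.
* Single linkage is the only clustering rule offered — it is the rule the
  barcode-gap threshold semantics imply, but it inherits single linkage's
  chaining behaviour when the gap assumption is violated.
* The simulator's star phylogenies make within- and between-species
  divergences exchangeable; real data have phylogenetic structure between
  species that the preset does not attempt to mimic.
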