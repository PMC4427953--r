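---
title: "Ranking disease-associated protein complexes: models and design"
author: "complexRank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking disease-associated protein complexes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexRank)
```

## The problem and the model

A protein complex is modeled as nothing more than a set of gene
identifiers (its subunits), and a disease as a set of genes. The method
rests on two assumptions:

1. **Association by subunit.** A complex is treated as disease-associated
   as soon as one subunit is a known disease gene. This is a deliberate,
   coarse rule: it yields seed sets without any curated complex–disease
   resource, at the price of making seeds correlated with each other
   whenever a disease gene belongs to several complexes (consequences are
   analysed under *Limitations*).
2. **Guilt by association.** Complexes associated with the same disease
   are functionally similar, so in a network whose edges encode
   functional similarity they sit close together, and proximity to known
   seeds predicts new associations.

Three views of "functionally similar" are implemented, each producing an
undirected weighted network over complexes with weights in (0, 1]:

* **Shared subunits** — overlap of the two subunit sets normalized by the
  smaller set. Captures physical overlap of the complexes themselves, and
  produces a sparse network (most complex pairs share nothing).
* **Shared GO annotations** — the same normalized overlap applied to each
  complex's *annotation closure*: the union over subunits of direct GO
  terms plus all ancestors along `is_a`/`part_of` edges, excluding the
  three sub-ontology roots (which annotate everything and carry no
  information). One network is built per sub-ontology and the three are
  integrated by per-edge average, where the denominator is the number of
  networks actually containing the edge — an edge present only in BP is
  not diluted by its absence from CC and MF.
* **PPI proximity** — the mean of inverse shortest-path distances between
  the two subunit sets in a protein-interaction graph, with distance
  fixed at 1 for identical subunits or subunits the two complexes share,
  and infinite (contribution 0) for pairs with no connecting path or
  absent from the PPI entirely. Because closures and PPI paths connect
  almost any two complexes at least weakly, these two networks are
  near-complete; `thresholdNetwork()` extracts sparser versions.

## Ranking algorithms

Given seeds S, candidates are scored by one of:

* **NBH** — the sum of direct edge weights to seeds. Local,
  parameter-free, linear in the number of edges.
* **RWR** — random walk with restart: `P ← (1 − γ) Ŵᵀ P + γ P⁰`, with Ŵ
  the row-normalized adjacency and P⁰ uniform over seeds. The restart
  probability γ (default 0.9) controls locality: high γ keeps mass near
  the seeds.
* **PRINCE** — `P ← α W̃ P + (1 − α) P⁰` with the symmetric degree
  normalization `W̃ = D^{-1/2} W D^{-1/2}`. The trade-off α (default 0.1)
  weighs smoothing against the prior; because the spectral radius of W̃
  is at most 1, the iteration converges for any α < 1.

The defaults γ = 0.9 and α = 0.1 are the locality-favouring ends of the
usual (0.1–0.9) grids, which is also where both algorithms behave most
like NBH; `evaluateSuite()` sweeps grids explicitly rather than trusting
any single value.

**Orientation.** With a non-symmetric row-normalized operator, "propagate"
can mean mixing in-flows or out-flows. The package multiplies by the
*transpose* of the row-normalized matrix, i.e. probability mass leaves
each node along that node's own normalized out-weights — the standard
column-stochastic walker semantics. On these undirected networks the
choice affects scores only through degree weighting, but it is fixed and
documented here because rankings do differ between the two readings.

## Evaluation

Leave-one-out cross-validation per disease: with seed set D, each s ∈ D
is held out, S = D∖{s} becomes the source set, and the fixed candidate
set C = V∖D plus s is ranked (midranks under ties, so a rank sum is
always n(n+1)/2). Counts are pooled across folds — TP/FN over the |D|
held-out ranks, FP/TN over the |D|·|C| candidate ranks — and sensitivity
versus 1 − specificity is traced by sweeping the rank threshold.

Numerical choices:

* The threshold sweeps **every distinct observed rank value** rather than
  only the integers 1..|C ∪ {s}|. With integer ranks the two sweeps are
  identical; with midranks the observed-rank sweep makes the trapezoidal
  AUC exactly the tie-corrected Mann–Whitney statistic (ties credited
  1/2), which is the property the test suite verifies against an O(n²)
  pairwise oracle.
* Pooling, not averaging: the count formulas sum over all held-out runs
  before sensitivity/specificity are formed; per-fold curves are never
  averaged. The alternative (averaging per-fold AUCs) would weight folds
  equally regardless of tie structure; the pooled reading matches the
  count definitions and keeps the Mann–Whitney correspondence.
* Propagation converges on an L1 change below 10⁻⁶ with a hard cap of
  10,000 iterations (exceeding the cap raises an error rather than
  returning a half-converged vector).
* Candidates missing from a network score 0 and are ranked by midrank
  below any positive-scoring node, so rankings can span the full complex
  universe even though isolated complexes are dropped from built
  networks by default (`keepIsolated = TRUE` retains them).
* Seeds falling outside a network are ignored by the scorers; a fold
  whose sources are all outside yields an all-zero score vector, which
  the midrank machinery turns into a chance-level (not zero) fold.

Algorithm and network comparisons use the Welch two-sample t statistic
with Welch–Satterthwaite degrees of freedom on per-disease AUC samples
(`welchTTest()`, cross-checked in the tests against `stats::t.test`).
Case studies are calibrated by `randomSetBaseline()`: repeated uniform
draws of k complexes, hit counts per draw, and a two-sided one-sample
t-test of the random mean against the observed top-k count, under a
caller-supplied seed (default 42).

## The synthetic generator

`generateSyntheticData()` emulates the five external inputs. Genes are
partitioned into clusters of about 20; each complex anchors one cluster
and draws its 3–8 subunits (CORUM-like sizes, median 5) from the cluster
pool with geometric rank decay plus a 15% uniform leak. The decay is what
creates realistic membership overlap: uniformly sampled complexes of this
size over 500 genes would almost never share a subunit and the
shared-subunit network would be empty. GO annotations follow the same
clusters (each cluster has a small term signature per sub-ontology, plus
noise terms), and the PPI is a sparse background graph densified within
clusters, so a single fixture exercises all three network modes. Diseases
anchor a cluster too: each disease gene comes from the cluster core with
probability equal to the **cohesion** parameter, else uniformly from all
genes. Cohesion 1 plants a tight module whose seed complexes are mutual
neighbors; cohesion 0 scatters the genes.

Default sizes (500 genes, 150 complexes, 20 diseases of 4 genes) are the
package's standing study conditions: large enough that LOOCV pools
hundreds of candidate ranks per disease, small enough that the full test
suite and the acceptance script run in minutes on one CPU.

What the generator does **not** emulate: CORUM's size distribution tail
(very large complexes), scale-free PPI topology, evidence codes and
annotation bias in gene2go, or phenotype structure in OMIM. Passing tests
therefore demonstrate correctness of the machinery and recoverability of
planted signal — not performance on real 2015-era database snapshots,
whose published node/edge counts and AUC values are snapshot-specific and
are not reproduced here.

## Limitations

* **The cohesion-0 null is not chance level.** Under the
  association-by-subunit rule, any disease gene belonging to two or more
  complexes makes *all* of its host complexes seeds, and in LOOCV the
  held-out one is then adjacent to a source through that very gene. With
  any complex catalogue dense enough to have a non-empty shared-subunit
  network (here: mean gene multiplicity ≈ 1.6), uniformly scattered
  disease genes still yield above-chance AUC. The acceptance suite
  documents this: mean NBH AUC rises monotonically with cohesion and
  exceeds 0.85 at cohesion 1, but the cohesion-0 check against 0.5 fails
  — a property of the seed-derivation rule, not of the generator or the
  ranking algorithms. Real-data AUCs obtained under this rule inherit
  the same optimism.
* Pairwise network construction is O(n²) in the number of complexes
  (with an inverted index so only intersecting pairs are scored in the
  overlap modes); it is meant for catalogues of a few thousand
  complexes, not for millions of nodes.
* GO similarity is pure closure overlap; no information-content
  weighting, so shallow, frequent terms count as much as specific ones —
  one reason the GO network is near-complete and benefits from
  thresholding.
* Identifiers are opaque, case-sensitive strings; mapping between symbol
  and Entrez namespaces is the caller's responsibility.
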