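---
title: "Methods: synteny, rearrangement and pan-genome dynamics of linear bacterial chromosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synteny, rearrangement and pan-genome dynamics of linear bacterial chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linsyn)
library(dplyr)
```

## The biological problem

Actinomycetes such as *Streptomyces* carry a single large linear
chromosome (6–12 Mb) with a characteristic architecture: a central
region concentrating the conserved, vertically inherited genes, flanked
by two chromosomal arms (subtelomeres) enriched in accessory genes and
capped by terminal inverted repeats (TIRs). Comparative evidence
indicates that inversions, gene gains (horizontal transfer) and gene
losses accumulate preferentially towards the telomeres — a
*recombination gradient* — so that strains diverging from a common
ancestor differentiate fastest in their terminal regions while the
central gene skeleton stays comparatively stable.

`linsyn` implements the quantitative toolkit used to study this
phenomenon — average nucleotide identity, reciprocal-best-hit orthology,
pan/core-genome rarefaction, core-region delimitation, sliding-window
synteny indexes, DCJ rearrangement distances and portion-wise
evolutionary-rate regressions — together with a simulator of
linear-chromosome evolution that provides complete ground truth, so that
every stage of the pipeline can be validated against data whose history
is known exactly.

## The simulator

`generate_ancestor()` lays out `n_core` core families in the central
`1 - 2 * arm_fraction` span of gene ranks, interleaved with accessory
families; the arms carry only accessory families. `evolve_tree()` then
walks a phylogeny from the root. On a branch of length $b$ over a
chromosome of $n$ genes, the number of events of each type is Poisson
with mean $\mathrm{rate} \times b \times n$, so rates are expected
events *per gene per unit branch length*.

Event positions follow the gradient weight on relative rank
$x \in [0, 1]$:

$$g(x) = \left(2\,|x - 0.5|\right)^\beta,$$

with $\beta$ = `gradient_exponent`. $\beta = 0$ recovers a uniform
distribution; $\beta = 3$ (the default) concentrates events strongly in
the arms. The form is the simplest single-parameter family that is
symmetric about the centre, vanishes there for $\beta > 0$, and is
maximal at both telomeres, matching the verbal description of the
gradient; a vanishing tiny floor ($10^{-9}$) keeps the sampling
distribution proper.

Design choices worth making explicit:

* **Losses spare the core.** Core families are by definition present in
  every genome, so the simulator never deletes them; they remain
  *movable* by inversions, which is what lets the category-wise DCJ
  analysis observe core-gene shuffling separately from content change.
* **Inversions are local.** The first breakpoint is gradient-weighted;
  the segment length is geometric (mean `inversion_mean_genes`, default
  5 genes) extending in a random direction, capped at the chromosome
  end. Sampling *both* breakpoints independently from the gradient was
  considered and rejected: with weights concentrated at the two ends,
  independent breakpoints routinely span the centre and would invert the
  entire central region, destroying precisely the central conservation
  the model is supposed to produce. No length model is implied by the
  biology beyond "inversions are predominantly local", which the
  geometric choice encodes with one parameter.
* **Gains draw from a finite HGT pool without replacement**, so every
  gained family is novel and single-copy; combined with loss-only
  removal this keeps every family single-copy per genome, and the truth
  orthology (`truth_orthology()`) is exactly one-to-one.
* **Determinism.** Each branch derives its own RNG stream seed from the
  root seed and the child-node label, so the whole truth set is
  reproducible from `params$seed` regardless of traversal internals.

`emit_sequences()` adds a sequence layer: each family receives a random
stop-free coding sequence that accumulates point substitutions at
`subst_rate` per site per unit branch length; genomes are gene + spacer
concatenations matching the gene-table coordinates. When
`tir_length_bp > 0` the reverse complement of the first `tir_length_bp`
bases is appended at the right end. The 20 bases immediately inside the
repeat copy are forced to mismatch their inverted-repeat counterparts
(a "divergence guard"): without it, chance matches just beyond the
planted repeat make the *true* maximal TIR of the emitted sequence
longer than the parameter, and an exact round trip through
`detect_tir()` would be ill-posed rather than merely noisy. The guard
makes the parameter the true TIR length by construction.

### What the simulator does and does not emulate

It reproduces the features the downstream statistics rely on: a single
linear replicon, a centrally concentrated conserved skeleton, arms
enriched in accessory genes, telomere-biased indels and inversions,
TIRs, and sequence divergence proportional to branch length. It does
**not** model nucleotide-level indels, selection, paralogy, gene-length
variation, annotation error, or arm-replacement events between
replicons. Passing tests on synthetic data therefore validate the
*computations*; they do not certify behaviour on real annotations with
paralogues or fragmented assemblies.

## ANIb and terminal inverted repeats

`fragment_genome()` cuts the query into 1000 contiguous fragments whose
lengths differ by at most 1 bp (the remainder is spread one base each
over the last fragments). `anib_oneway()` keeps, per fragment, the best
hit by bitscore and averages the percent identity of fragments whose
best hit aligns **more than 70 %** of the fragment with **at least
30 %** identity; fragments with no qualifying hit are excluded, and a
direction with no qualifying fragment is *undefined* (`NA`), never 0.
The pair score is the mean of the two one-way scores, which are not
reciprocal. Alignment is delegated to an injected aligner
(`blast_aligner()` wraps `blastn`); any function with the same contract
can be substituted. Species dereplication (`cluster_species()`) uses
single linkage over the $\ge 96\,\%$ relation — the weakest assumption
consistent with "sharing $\ge 96\,\%$ means conspecific" — and picks the
largest genome as the cluster representative.

`detect_tir()` compares the prefix with the reverse complement of the
equal-length suffix position by position (both repeats are anchored at
the termini) and reports the longest length $L \ge$ `min_len` whose
cumulative identity is $\ge$ `min_identity` *and* whose last position
matches — a repeat ends on a matching base. This anchored scan is linear
in the sequence and avoids quadratic alignment over megabases.
`trim_tir()` removes the right-hand copy; genes fully inside it are
dropped and a gene straddling the boundary is truncated out with a
warning.

## Orthology, families and the core-region

`bbh_orthologs()` applies the classical reciprocal-best-hit rule with
identity $\ge 40\,\%$, coverage $\ge 70\,\%$ **of both query and
subject** (the symmetric reading keeps the rule consistent under
direction swap), and E-value $< 10^{-10}$; best hits are ranked by
bitscore with ties broken by identity then subject id, so the map is
invariant under permutation of the input hits. Families
(`build_families()`) are connected components of the union of pairwise
maps; a component with two genes from one genome is kept but flagged,
preserving auditability instead of silently splitting.

The core-genome is the set of families present in every genome; the
**core-region** (`core_region()`) is the *shortest* contiguous rank
interval containing $\lceil 0.95\,C \rceil$ of the chromosome's $C$
core genes. The ceiling guarantees "at least 95 %", and the
minimal-span reading (rather than trimming 2.5 % from each end) is the
one that avoids overestimating the region's extent; ties on span are
broken toward the interval whose midpoint is most central. Arms are the
flanking regions, and a chromosome is *unbalanced* when one arm is at
least twice the other. The implementation slides over core genes in
$O(C)$; tests compare it against an exhaustive $O(n^2)$ interval search.

`rarefaction()` draws, for each subset size $n$, 100 independent random
$n$-subsets (without replacement within a subset) and records core and
pan sizes; `heaps_fit()` fits $\log \mathrm{pan} = \log\kappa + \gamma
\log n$ by least squares, with $\gamma > 0$ indicating an open
pan-genome.

## Synteny indexes

All three indexes compare a reference chromosome with another genome
through an orthology map, in windows sliding along the reference:

* **OR** — fraction of window genes with an orthologue. Content only:
  it is invariant under any permutation of the compared genome.
* **GOC** — among the window's orthologues, the fraction involved in at
  least one *conserved adjacency*: a rank-adjacent reference pair whose
  images' ranks in the compared genome also differ by exactly 1.
  Counting *genes* involved in pairs (not pairs) keeps the ratio within
  $[0, 1]$ by construction. A window with no orthologue is `NA`
  (non-applicable), not 0. Orientation is deliberately ignored here —
  contiguity is positional; orientation enters through DCJ.
* **NOC** — like GOC but computed over the *considered* genes only:
  mapped genes with at least one mapped rank-neighbour. Isolated
  orthologues are excluded, which keeps the index defined and
  comparable under sparse orthology where most GOC windows are `NA`.
  NOC windows contain a fixed number of considered genes, so their
  physical extent varies and the profile is anchored on ordinal window
  numbers, not chromosomal positions.

Window sizes are percentages of the relevant gene count
(round-half-up, minimum one gene); OR/GOC slide by one gene, NOC by
0.1 % of the considered genes. Only complete windows are emitted: the
chromosome is linear, and wrapping windows around would fabricate
adjacency across the telomeres. Heatmap summaries
(`profile_heatmap_table()`) average window values in 100 percentile
bins of the reference length and order compared genomes by cophenetic
distance.

## DCJ distances

`extract_marker_orders()` restricts a genome pair to its mapped genes
(optionally one of the three categories: core genes, non-core
orthologues inside the core-region, orthologues in the arms), relabels
markers by reference rank, and takes orientations from gene strands
with both chromosomes read left-telomere-first. Families flagged as
inconsistent are excluded upstream — DCJ requires equal, single-copy
content. `dcj_distance()` builds the adjacency graph over marker
extremities and applies

$$d = n - C - I/2,$$

with $C$ cycles and $I$ odd paths. The distance, not any sorting
scenario, is what the analyses use; the value is divided by the marker
count (`normalized_dcj()`) so that pairs with different orthologue
counts are comparable — this per-marker normalization is the only
weighting applied. An independent reference implementation
(`dcj_distance_search()`) finds shortest operation sequences by
breadth-first search over genuine DCJ operations on adjacency/telomere
matchings; tests require exact agreement with the formula on every
signed order up to $n = 5$ and on random instances at $n = 6$.

## Portion-wise trends

`split_portions()` cuts the reference into $k$ contiguous blocks of
equal gene counts (sizes differ by at most one; the remainder goes one
gene each to the last blocks — the rule is arbitrary but deterministic).
`portion_index_scan()` evaluates OR/GOC over each portion *as a single
window*, and `fit_trend()` regresses values against cophenetic distance
with a degree-3 polynomial (degree 2 for the DCJ trends), reporting
additionally the **early slope** $\alpha$: the slope of an ordinary
linear fit restricted to distances in $[0, 0.1]$.

The early slope is deliberately a secant estimator, not the
polynomial's derivative at zero. For values generated as
$1 - 5d + 30d^2$ with distances uniform on $[0, h]$, the population
slope of the linear fit is $-5 + 30h$ (because
$\mathrm{cov}(d, d^2)/\mathrm{var}(d) = h$), i.e. $-2$ at $h = 0.1$:
curvature inside the early range is absorbed into the secant. This
linearization bias is intrinsic to fitting a line over a finite range
and is documented rather than corrected; comparisons *between* portions
use the same estimator and are unaffected.

## Numerical and edge-case policies

* Coordinates are 1-based inclusive (GFF3); ranks 0-based from the left
  telomere. Reading a gene table sorts by start and reassigns ranks;
  re-reading a sorted table is idempotent.
* Duplicate gene ids, `start > end`, and unknown strand symbols are
  errors; overlapping genes are allowed.
* Best-hit and clustering tie-breaks are lexicographic after the
  quantitative criteria, so every result is order-independent.
* `anib_oneway()` with no qualifying fragment, GOC windows without
  orthologues, empty NOC profiles and empty DCJ categories all
  propagate as `NA`/empty rather than 0 — absence of evidence is kept
  distinct from measured dissimilarity.
* Degenerate fits: constant values give an early slope of exactly 0;
  fewer points than parameters is an error.

## Problem sizes used in validation

The shipped tests and the acceptance script run at desk scale, chosen
so the full suite completes in minutes while every qualitative contrast
is detected with wide margins: ancestral chromosomes of 600 genes
(300 core / 300 accessory, arms of 25 % each), 20-leaf coalescent
trees of depth 0.3, default rates (0.1 inversions, 0.2 gains, 0.2
losses per gene per unit branch length, $\beta = 3$), 100 rarefaction
iterations, DCJ oracle equivalence exhaustively to $n = 5$ plus 500
random $n = 6$ instances, and 60 kb genomes for the blastn-backed ANIb
checks. At these sizes the arm-versus-centre contrasts (Mann–Whitney
$p < 10^{-100}$, arm DCJ three- to four-fold above core DCJ) are far
from their decision thresholds.

## Known limitations

* Families are connected components of pairwise BBH maps; a
  reference-anchored or tree-aware family construction could differ on
  real data with paralogues.
* The TIR scan requires terminal anchoring; repeats displaced from the
  sequence ends (assembly artefacts) are not found.
* Trend fitting is ordinary least squares; no phylogenetic correction
  (PGLS) is applied, and points sharing a reference genome are not
  independent. The analyses use the fits descriptively.
* The restricted DCJ variant (no circular intermediates) affects
  sorting scenarios, not the distance on single linear chromosomes; the
  package computes distances only.

## A worked example

```{r example, eval = FALSE}
params <- evolution_params(seed = 101)
tree <- sim_tree(20, depth = 0.3, seed = 101)
truth <- evolve_tree(generate_ancestor(params), tree, params)

ref_id <- names(truth$chromosomes)[1]
ref <- truth$chromosomes[[ref_id]]
others <- truth$chromosomes[setdiff(names(truth$chromosomes), ref_id)]
maps <- sapply(names(others), function(b)
  truth_orthology(truth, ref_id, b), simplify = FALSE)

# arm erosion visible in a sliding OR profile
autoplot(or_profile(ref, others[[1]], maps[[1]]))

# portion-wise early slopes (steeper in portions 1 and 6)
scan <- portion_index_scan(ref, others, maps, split_portions(ref, 6),
                           "OR", tree = tree)
portion_trends(scan, degree = 3)
```
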