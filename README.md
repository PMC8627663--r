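# linsyn

Synteny, rearrangement and pan-genome dynamics of **linear bacterial
chromosomes**.

Actinomycetes such as *Streptomyces* carry a single linear chromosome
(6–12 Mb) with a striking architecture: a central region concentrating
the conserved gene skeleton, flanked by fast-evolving chromosomal arms
(subtelomeres) enriched in accessory genes and capped by terminal
inverted repeats (TIRs). Inversions, gene gains and losses accumulate
preferentially towards the telomeres — a recombination gradient — so
that related strains diverge fastest at their chromosome ends.

`linsyn` is a tidyverse-style toolkit for quantifying this phenomenon,
plus a ground-truthed simulator for validating every stage:

* **ANIb & dereplication** — fragment-based average nucleotide identity
  (1000 fragments, best-hit identities averaged over fragments aligning
  \>70 % with ≥30 % identity; the pair score is the mean of the two
  non-reciprocal one-way scores), single-linkage species clustering at
  96 % (`fragment_genome()`, `anib_pair()`, `cluster_species()`).
* **TIRs** — anchored detection of terminal inverted repeats at ≥99 %
  identity and single-copy trimming (`detect_tir()`, `trim_tir()`).
* **Orthology & pan-genome** — blastp reciprocal best hits (≥40 %
  identity, ≥70 % coverage, E < 1e−10), gene families as connected
  components, pan/core rarefaction (100 random subsets per size),
  Heap's law fit pan(n) ≈ κ·n^γ (`bbh_orthologs()`,
  `build_families()`, `rarefaction()`, `heaps_fit()`).
* **Core-region** — the shortest rank interval containing 95 % of a
  chromosome's core genes; arms and typical/unbalanced architecture
  (`core_region()`, `classify_architecture()`).
* **Synteny indexes** — sliding-window orthology rate (OR), gene order
  conservation (GOC) and neighbour orthologue conservation (NOC),
  with percentile-binned heatmap tables ordered by cophenetic distance
  (`or_profile()`, `goc_profile()`, `noc_profile()`,
  `profile_heatmap_table()`).
* **DCJ** — double-cut-and-join distance d = n − C − I/2 on shared
  markers, normalized by marker count, with the three-category scan
  (core genes / non-core orthologues in the core-region / arm
  orthologues) and an exhaustive breadth-first-search reference
  implementation (`dcj_distance()`, `category_dcj_scan()`,
  `dcj_distance_search()`).
* **Portion-wise trends** — k equal-gene portions, per-portion OR/GOC
  against cophenetic distance, degree-3 polynomial fits and the early
  slope α over distances 0–0.1 (`split_portions()`,
  `portion_index_scan()`, `fit_trend()`, `portion_trends()`).
* **Simulator** — linear chromosomes evolving along a phylogeny under a
  telomere gradient g(x) = (2|x−0.5|)^β: gradient-placed inversions,
  HGT gains and losses over a loss-exempt core skeleton, with emitted
  genome/protein sequences and exact truth orthology
  (`evolution_params()`, `generate_ancestor()`, `evolve_tree()`,
  `emit_sequences()`).

Results are tibbles; fitted objects support `tidy()`/`glance()`;
profiles and fits have `autoplot()`/`plot_*()` methods.

## A worked example

Simulate 20 genomes under a steep gradient (β = 3), then ask whether
the terminal sixths of the chromosome behave differently from the
centre:

```r
library(linsyn)
library(dplyr)
library(purrr)

params <- evolution_params(seed = 101)          # 600-gene ancestor, beta = 3
tree   <- sim_tree(20, depth = 0.3, seed = 101)
truth  <- evolve_tree(generate_ancestor(params), tree, params)
leaves <- names(truth$chromosomes)

# per-portion OR for every ordered genome pair, k = 6 equal-gene portions
scan <- map_dfr(leaves, function(r) {
  ref    <- truth$chromosomes[[r]]
  others <- truth$chromosomes[setdiff(leaves, r)]
  maps   <- sapply(names(others), function(b) truth_orthology(truth, r, b),
                   simplify = FALSE)
  portion_index_scan(ref, others, maps, split_portions(ref, 6),
                     "OR", tree = tree)
})

scan |>
  group_by(portion) |>
  summarise(mean_or = mean(value),
            alpha_early = fit_trend(
              tibble::tibble(distance = cophenetic_distance, value = value),
              degree = 3)$alpha_early)
#> # A tibble: 6 × 3
#>   portion mean_or alpha_early
#>     <int>   <dbl>       <dbl>
#> 1       1   0.846     -0.331
#> 2       2   0.964     -0.0606
#> 3       3   1.000      0
#> 4       4   0.996     -0.0366
#> 5       5   0.965     -0.0447
#> 6       6   0.849     -0.517
```

The two terminal portions (1 and 6) have visibly lower mean orthology
rates than the central portions and lose orthologues several times
faster at short phylogenetic distances (early slopes −0.33 and −0.52
versus ~−0.05 in the centre): the simulated recombination gradient is
recovered by the portion analysis.

The pan-genome side of the same data:

```r
prof <- pangenome_profile(truth_gene_table(truth))
prof
#> <pangenome_profile> 20 genomes, 775 families (490 core, 0 flagged)

rarefaction(prof, iterations = 100, seed = 1) |>
  group_by(n) |>
  summarise(pan = median(pan_size)) |>
  heaps_fit() |>
  glance()
#> # A tibble: 1 × 4
#>   kappa  gamma r.squared n_points
#>   <dbl>  <dbl>     <dbl>    <int>
#> 1  611. 0.0807     0.997       19
```

γ > 0: the simulated pan-genome is open (gains keep adding novel
families as genomes accumulate).

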