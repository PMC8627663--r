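# OR / GOC / NOC sliding-window indexes.

test_that("the 8-gene toy gives OR 0.75, GOC 5/6, NOC 1", {
  toy <- fig_toy()
  orp <- or_profile(toy$ref, toy$other, toy$map, window_pct = 100)
  expect_equal(nrow(orp), 1L)
  expect_equal(orp$value, 0.75)

  gp <- goc_profile(toy$ref, toy$other, toy$map, window_pct = 100)
  expect_equal(gp$value, 5 / 6)

  np <- noc_profile(toy$ref, toy$other, toy$map)
  expect_true(all(np$value == 1))

  # the conserved adjacencies are exactly (r1,r2), (r2,r3), (r7,r8)
  adj <- conserved_adjacencies(toy$ref, toy$other, toy$map)
  expect_equal(adj$rank_i, c(0L, 1L, 6L))
})

test_that("self-comparison yields 1 everywhere for all three indexes", {
  st <- small_truth()
  ch <- st$truth$chromosomes[[1]]
  self <- identity_selfmap(ch)
  expect_true(all(or_profile(ch, ch, self)$value == 1))
  expect_true(all(goc_profile(ch, ch, self)$value == 1))
  expect_true(all(noc_profile(ch, ch, self)$value == 1))
  adj <- conserved_adjacencies(ch, ch, self)
  expect_equal(nrow(adj), nrow(ch) - 1L)
})

test_that("no shared orthologues gives OR 0 and an empty NOC profile", {
  ref <- toy_chromosome(20, "r")
  other <- toy_chromosome(20, "o")
  empty <- orthology_map(tibble::tibble(gene_a = character(0),
                                        gene_b = character(0)), "r", "o")
  expect_true(all(or_profile(ref, other, empty)$value == 0))
  expect_true(all(is.na(goc_profile(ref, other, empty, 100)$value)))
  expect_equal(nrow(noc_profile(ref, other, empty)), 0L)
  expect_equal(nrow(conserved_adjacencies(ref, other, empty)), 0L)
})

test_that("OR ignores gene order while GOC is order-sensitive", {
  ch <- toy_chromosome(40, "r")
  self <- identity_selfmap(ch)
  withr::local_seed(47)
  perm <- permute_chromosome(ch, sample(0:39), "shuffled")
  map <- orthology_map(tibble::tibble(gene_a = ch$gene_id,
                                      gene_b = ch$gene_id), "r", "shuffled")
  expect_true(all(or_profile(ch, perm, map)$value == 1))
  expect_lt(mean(goc_profile(ch, perm, map)$value), 1)

  # a single internal inversion of >= 2 genes removes exactly 2 adjacencies
  inv <- c(0:9, 19:10, 20:39)
  inverted <- permute_chromosome(ch, inv, "inv")
  map2 <- orthology_map(tibble::tibble(gene_a = ch$gene_id,
                                       gene_b = ch$gene_id), "r", "inv")
  adj <- conserved_adjacencies(ch, inverted, map2)
  expect_equal(nrow(adj), 39L - 2L)
  expect_true(all(or_profile(ch, inverted, map2)$value == 1))
})

test_that("windows are complete, anchored on central genes, NA where empty", {
  ch <- toy_chromosome(100, "r")
  other <- toy_chromosome(100, "o")
  # orthologues only in the left half
  map <- orthology_map(
    tibble::tibble(gene_a = ch$gene_id[1:50], gene_b = other$gene_id[1:50]),
    "r", "o")
  orp <- or_profile(ch, other, map, window_pct = 5)
  expect_equal(nrow(orp), 96L)           # only complete windows (w = 5)
  expect_true(all(orp$value >= 0 & orp$value <= 1))
  expect_true(!is.unsorted(orp$anchor_bp, strictly = TRUE))
  gp <- goc_profile(ch, other, map, window_pct = 5)
  expect_true(any(is.na(gp$value)))       # windows with no orthologue
  ok <- !is.na(gp$value)
  expect_true(all(gp$value[ok] >= 0 & gp$value[ok] <= 1))
})

test_that("NOC stays defined under sparse orthology where GOC is mostly NA", {
  withr::local_seed(53)
  n <- 300
  ch <- toy_chromosome(n, "r")
  other <- toy_chromosome(n, "o")
  # sparse orthology: a few short runs of mapped genes among a desert
  runs <- sort(unlist(lapply(sample(seq(1, n - 3, by = 30), 6),
                             function(s) s:(s + 2))))
  map <- orthology_map(
    tibble::tibble(gene_a = ch$gene_id[runs], gene_b = other$gene_id[runs]),
    "r", "o")
  gp <- goc_profile(ch, other, map, window_pct = 1)
  np <- noc_profile(ch, other, map)
  expect_gt(mean(is.na(gp$value)), 0.5)
  expect_gt(nrow(np), 0)
  expect_true(all(!is.na(np$value)))
})

test_that("a random permutation drives mean NOC near zero", {
  withr::local_seed(59)
  n <- 1000
  ch <- toy_chromosome(n, "r")
  perm <- permute_chromosome(ch, sample(0:(n - 1)), "rand")
  map <- orthology_map(tibble::tibble(gene_a = ch$gene_id,
                                      gene_b = ch$gene_id), "r", "rand")
  np <- noc_profile(ch, perm, map)
  expect_lt(mean(np$value), 0.05)
})

test_that("heatmap rows are percentile-binned and distance-ordered", {
  st <- small_truth()
  leaves <- names(st$truth$chromosomes)
  ref <- st$truth$chromosomes[[leaves[1]]]
  others <- st$truth$chromosomes[leaves[-1]]
  maps <- lapply(leaves[-1], function(b)
    truth_orthology(st$truth, leaves[1], b))
  names(maps) <- leaves[-1]
  tbl <- profile_heatmap_table(ref, others, maps, "OR", st$truth$tree)
  expect_true(all(tbl$bin >= 1 & tbl$bin <= 100))
  ord <- tbl |> dplyr::distinct(other, cophenetic_distance)
  expect_true(!is.unsorted(ord$cophenetic_distance))

  # a compared genome identical to the reference gives a row of ones
  selfmap <- list(identity_selfmap(ref))
  names(selfmap) <- leaves[1]
  tree2 <- st$truth$tree
  self_tbl <- profile_heatmap_table(
    ref, stats::setNames(list(ref), leaves[1]), selfmap, "OR", tree2)
  expect_true(all(self_tbl$value == 1))

  expect_error(
    profile_heatmap_table(ref, stats::setNames(list(ref), "nope"),
                          stats::setNames(selfmap, "nope"), "OR", tree2),
    "missing from tree")
})
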