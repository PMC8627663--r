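# Fixtures built in code: toy chromosomes, the classic 8-gene window
# example, and small helpers shared across test files.

# A chromosome of n genes with synthesized coordinates (1 kb pitch).
toy_chromosome <- function(n, genome_id = "toy", strands = NULL,
                           family_id = NULL) {
  genes <- tibble::tibble(
    gene_id = sprintf("%s_g%03d", genome_id, seq_len(n)),
    start = as.integer((seq_len(n) - 1L) * 1000L + 101L),
    end = as.integer((seq_len(n) - 1L) * 1000L + 1000L),
    strand = if (is.null(strands)) rep("+", n) else strands
  )
  if (!is.null(family_id)) genes$family_id <- family_id
  linear_chromosome(genes, genome_id = genome_id,
                    length_bp = n * 1000L + 100L)
}

identity_selfmap <- function(chrom) {
  orthology_map(
    tibble::tibble(gene_a = chrom$gene_id, gene_b = chrom$gene_id),
    chrom_genome_id(chrom), chrom_genome_id(chrom)
  )
}

# Reorder a chromosome's genes to a given rank permutation (perm[i] = the
# old rank, 0-based, placed at new rank i-1), resynthesizing coordinates.
permute_chromosome <- function(chrom, perm, genome_id = "perm") {
  src <- chrom[order(chrom$rank), ]
  genes <- src[perm + 1L, c("gene_id", "strand",
                            intersect("family_id", names(src)))]
  n <- nrow(genes)
  genes$start <- as.integer((seq_len(n) - 1L) * 1000L + 101L)
  genes$end <- genes$start + 899L
  genes$gene_id <- src$gene_id[perm + 1L]
  linear_chromosome(genes, genome_id = genome_id,
                    length_bp = n * 1000L + 100L)
}

# The 8-gene windowed toy: reference r1..r8; the compared genome carries
# orthologues of r1, r2, r3, r5, r7, r8 in an order that conserves the
# adjacencies (r1,r2), (r2,r3) and (r7,r8); r5's orthologue sits apart,
# isolated between genes without reference orthologues.
fig_toy <- function() {
  ref <- toy_chromosome(8, "refA")
  other <- toy_chromosome(8, "spB")
  # other order: o1=r1, o2=r2, o3=r3, o4=(unmapped), o5=r5, o6=(unmapped),
  # o7=r7, o8=r8 -> images of r1,r2,r3 adjacent; r7,r8 adjacent; r5 isolated
  map <- orthology_map(
    tibble::tibble(
      gene_a = paste0("refA_g00", c(1, 2, 3, 5, 7, 8)),
      gene_b = paste0("spB_g00", c(1, 2, 3, 5, 7, 8))
    ),
    "refA", "spB"
  )
  list(ref = ref, other = other, map = map)
}

# Exhaustive minimal-interval search for the core-region (oracle).
core_region_oracle <- function(chrom, is_core, fraction = 0.95) {
  ranks <- sort(chrom$rank[is_core])
  k <- ceiling(fraction * length(ranks))
  n <- nrow(chrom)
  best <- NULL
  for (s in 0:(n - 1)) {
    for (e in s:(n - 1)) {
      if (sum(ranks >= s & ranks <= e) >= k) {
        span <- e - s
        mid_off <- abs((s + e) / 2 - (n - 1) / 2)
        if (is.null(best) || span < best$span ||
            (span == best$span && mid_off < best$mid_off)) {
          best <- list(s = s, e = e, span = span, mid_off = mid_off)
        }
        break  # larger e only widens the interval for this s
      }
    }
  }
  best
}

# Random signed order over 1..n under the current RNG state.
random_signed_order <- function(n) {
  sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
}

# All signed orders on markers 1..n (n! * 2^n of them).
all_signed_orders <- function(n) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  signs <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
  out <- list()
  for (p in perms(seq_len(n))) {
    for (row in seq_len(nrow(signs))) {
      out[[length(out) + 1L]] <- p * signs[row, ]
    }
  }
  out
}

# Shared small simulation used by several test files (cached per session).
small_truth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- evolution_params(n_core = 60, n_accessory_init = 60,
                            rate_inversion = 0.15, rate_gain = 0.3,
                            rate_loss = 0.3, seed = 11L)
      anc <- generate_ancestor(p)
      tr <- sim_tree(6, depth = 0.3, seed = 5L)
      cache <<- list(params = p, truth = evolve_tree(anc, tr, p))
    }
    cache
  }
})
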