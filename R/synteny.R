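# Sliding-window synteny indexes: orthology rate (OR), gene order
# conservation (GOC) and neighbour orthologue conservation (NOC).

# Map the reference chromosome's ranks to the compared chromosome's ranks
# through an orthology map; NA where a gene has no orthologue.
rank_image <- function(ref, other, map) {
  a_rank <- stats::setNames(ref$rank, ref$gene_id)
  b_rank <- stats::setNames(other$rank, other$gene_id)
  img <- rep(NA_integer_, nrow(ref))
  idx <- match(map$gene_a, ref$gene_id)
  ok <- !is.na(idx)
  img[idx[ok]] <- b_rank[map$gene_b[ok]]
  img
}

#' Conserved adjacencies between two chromosomes
#'
#' A pair of rank-adjacent reference genes is a conserved adjacency when
#' both genes are mapped and their orthologues' ranks in the compared
#' genome differ by exactly 1. Orientation is ignored; contiguity is a
#' positional notion (orientation enters the DCJ analysis instead).
#'
#' @param ref,other [linear_chromosome()] objects.
#' @param map An [orthology_map()] from `ref` genes (`gene_a`) to `other`
#'   genes (`gene_b`).
#' @return Tibble with one row per conserved adjacency: `gene_i`,
#'   `gene_j`, `rank_i`, `rank_j` (reference ranks, `rank_j = rank_i + 1`).
#' @export
conserved_adjacencies <- function(ref, other, map) {
  img <- rank_image(ref, other, map)
  n <- nrow(ref)
  if (n < 2) {
    return(tibble::tibble(gene_i = character(0), gene_j = character(0),
                          rank_i = integer(0), rank_j = integer(0)))
  }
  i <- seq_len(n - 1L)
  conserved <- !is.na(img[i]) & !is.na(img[i + 1L]) &
    abs(img[i + 1L] - img[i]) == 1L
  ref_sorted <- ref[order(ref$rank), ]
  tibble::tibble(
    gene_i = ref_sorted$gene_id[i][conserved],
    gene_j = ref_sorted$gene_id[i + 1L][conserved],
    rank_i = ref_sorted$rank[i][conserved],
    rank_j = ref_sorted$rank[i + 1L][conserved]
  )
}

# Per-reference-gene flags used by all three indexes, in rank order:
# mapped, in_pair (participates in >= 1 conserved adjacency), considered
# (mapped with >= 1 mapped rank-neighbour).
synteny_flags <- function(ref, other, map) {
  ref_sorted <- ref[order(ref$rank), ]
  img <- rank_image(ref_sorted, other, map)
  n <- nrow(ref_sorted)
  mapped <- !is.na(img)
  adj <- if (n >= 2) {
    i <- seq_len(n - 1L)
    mapped[i] & mapped[i + 1L] & abs(img[i + 1L] - img[i]) == 1L
  } else logical(0)
  in_pair <- rep(FALSE, n)
  if (n >= 2) {
    in_pair[which(adj)] <- TRUE
    in_pair[which(adj) + 1L] <- TRUE
  }
  nb_mapped <- rep(FALSE, n)
  if (n >= 2) {
    nb_mapped <- (c(FALSE, mapped[-n]) | c(mapped[-1], FALSE))
  }
  tibble::tibble(
    gene_id = ref_sorted$gene_id, rank = ref_sorted$rank,
    anchor_bp = as.integer((ref_sorted$start + ref_sorted$end) / 2),
    mapped = mapped, in_pair = in_pair,
    considered = mapped & nb_mapped
  )
}

window_size <- function(count, pct) {
  max(1L, as.integer(floor(count * pct / 100 + 0.5)))
}

new_window_profile <- function(tbl, index_kind, ref_id, other_id,
                               window_spec) {
  structure(tbl, index_kind = index_kind, ref = ref_id, other = other_id,
            window_spec = window_spec,
            class = c("window_profile", class(tibble::tibble())))
}

#' Orthology rate (OR) sliding-window profile
#'
#' OR is the fraction of reference-window genes having an orthologue in
#' the compared genome, in a window of `window_pct` % of the reference
#' gene count sliding with a one-gene step. Windows are anchored at the
#' chromosomal position of their central gene; only complete windows are
#' emitted (the chromosome is linear, no wraparound).
#'
#' @inheritParams conserved_adjacencies
#' @param window_pct Window size as a percent of the reference gene count
#'   (round-half-up, minimum 1 gene).
#' @return A `window_profile` tibble: `anchor_bp`, `value`.
#' @export
or_profile <- function(ref, other, map, window_pct = 5) {
  fl <- synteny_flags(ref, other, map)
  n <- nrow(fl)
  w <- window_size(n, window_pct)
  if (w > n) stop("window larger than the gene count")
  num <- slide_sum(fl$mapped, w)
  centre <- seq_len(n - w + 1L) + (w - 1L) %/% 2L
  new_window_profile(
    tibble::tibble(anchor_bp = fl$anchor_bp[centre], value = num / w),
    "OR", chrom_genome_id(ref), chrom_genome_id(other),
    paste0(window_pct, "% of genes")
  )
}

#' Gene order conservation (GOC) sliding-window profile
#'
#' GOC divides the number of window orthologues involved in conserved
#' contiguous pairs by the number of orthologues in the window. A gene
#' counts as "involved" when it participates in at least one conserved
#' adjacency (the adjacency may straddle the window edge). Windows with
#' no orthologue are non-applicable (`NA`).
#'
#' @inheritParams or_profile
#' @return A `window_profile` tibble: `anchor_bp`, `value` (`NA` allowed).
#' @export
goc_profile <- function(ref, other, map, window_pct = 5) {
  fl <- synteny_flags(ref, other, map)
  n <- nrow(fl)
  w <- window_size(n, window_pct)
  if (w > n) stop("window larger than the gene count")
  num <- slide_sum(fl$mapped & fl$in_pair, w)
  den <- slide_sum(fl$mapped, w)
  centre <- seq_len(n - w + 1L) + (w - 1L) %/% 2L
  new_window_profile(
    tibble::tibble(anchor_bp = fl$anchor_bp[centre],
                   value = ifelse(den > 0, num / den, NA_real_)),
    "GOC", chrom_genome_id(ref), chrom_genome_id(other),
    paste0(window_pct, "% of genes")
  )
}

#' Neighbour orthologue conservation (NOC) profile
#'
#' NOC restricts attention to the "considered" genes: reference genes with
#' an orthologue whose rank-neighbour on at least one side also has an
#' orthologue (isolated orthologues are excluded). Windows hold
#' `window_pct` % of the considered genes and advance by `step_pct` % of
#' them (at least one gene); the value is the fraction of the window's
#' genes participating in a conserved adjacency. Because window extents
#' vary in physical size, anchors are ordinal window numbers, not
#' chromosomal positions.
#'
#' @inheritParams or_profile
#' @param step_pct Step as a percent of the considered genes.
#' @return A `window_profile` tibble: `window` (ordinal), `value`.
#' @export
noc_profile <- function(ref, other, map, window_pct = 5, step_pct = 0.1) {
  fl <- synteny_flags(ref, other, map)
  cons <- fl[fl$considered, ]
  m <- nrow(cons)
  if (m == 0) {
    return(new_window_profile(
      tibble::tibble(window = integer(0), value = numeric(0)),
      "NOC", chrom_genome_id(ref), chrom_genome_id(other),
      paste0(window_pct, "% of considered genes")
    ))
  }
  w <- window_size(m, window_pct)
  step <- max(1L, as.integer(floor(m * step_pct / 100 + 0.5)))
  starts <- seq.int(1L, m - w + 1L, by = step)
  vals <- vapply(starts, function(s) {
    mean(cons$in_pair[s:(s + w - 1L)])
  }, numeric(1))
  new_window_profile(
    tibble::tibble(window = seq_along(starts), value = vals),
    "NOC", chrom_genome_id(ref), chrom_genome_id(other),
    paste0(window_pct, "% of considered genes")
  )
}

# Windowed running sum of a logical/numeric vector, window w, step 1.
slide_sum <- function(x, w) {
  cs <- cumsum(c(0, as.numeric(x)))
  cs[(w + 1L):length(cs)] - cs[seq_len(length(cs) - w)]
}

#' Percentile-binned profile matrix ordered by phylogenetic distance
#'
#' Bins each pairwise OR/GOC profile into 100 percentile bins of the
#' reference chromosome length (per-bin mean of window values, `NA`
#' propagated when a bin holds no defined value) and stacks the compared
#' genomes as rows, ordered from the phylogenetically closest to the
#' farthest using cophenetic distances from the tree.
#'
#' @param ref Reference [linear_chromosome()].
#' @param others Named list of compared [linear_chromosome()] objects.
#' @param maps Named list of [orthology_map()]s (ref vs each compared),
#'   keyed like `others`.
#' @param index_kind `"OR"` or `"GOC"`.
#' @param tree An [ape::phylo] containing the reference and all compared
#'   genomes.
#' @param window_pct Passed to the profile function.
#' @return Tibble: `other`, `cophenetic_distance`, `bin` (1..100),
#'   `value`; rows ordered by increasing distance.
#' @export
profile_heatmap_table <- function(ref, others, maps, index_kind = "GOC",
                                  tree, window_pct = 5) {
  stopifnot(index_kind %in% c("OR", "GOC"))
  ids <- names(others)
  missing <- setdiff(c(chrom_genome_id(ref), ids), tree$tip.label)
  if (length(missing) > 0) {
    stop("genome(s) missing from tree: ", paste(missing, collapse = ", "))
  }
  d <- cophenetic_matrix(tree)[chrom_genome_id(ref), , drop = TRUE][ids]
  prof_fun <- if (index_kind == "OR") or_profile else goc_profile
  len <- chrom_length(ref)
  rows <- lapply(ids, function(id) {
    p <- prof_fun(ref, others[[id]], maps[[id]], window_pct = window_pct)
    bin <- pmin(100L, pmax(1L, ceiling(p$anchor_bp / len * 100)))
    tibble::tibble(other = id, cophenetic_distance = d[[id]],
                   bin = bin, value = p$value) |>
      dplyr::group_by(.data$other, .data$cophenetic_distance, .data$bin) |>
      dplyr::summarise(
        value = if (all(is.na(.data$value))) NA_real_
                else mean(.data$value, na.rm = TRUE),
        .groups = "drop"
      )
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$cophenetic_distance, .data$other, .data$bin)
}
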