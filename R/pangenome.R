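# Gene families, pan/core-genome rarefaction, Heap's law, core-region
# delimitation and chromosome architecture classification.

#' Pan-genome profile from a family-labelled gene table
#'
#' @param gene_table Tibble with columns `genome_id`, `gene_id`,
#'   `family_id` (e.g. [truth_gene_table()] output, or the result of
#'   [build_families()]).
#' @return A list of class `pangenome_profile`: `membership` (the input
#'   columns), `presence` (long tibble `family_id`, `genome_id`,
#'   `n_genes`), `genomes`, `families`, `core_families` (families present
#'   in every genome), `inconsistent_families` (families with more than
#'   one gene in some genome).
#' @export
pangenome_profile <- function(gene_table) {
  stopifnot(all(c("genome_id", "gene_id", "family_id") %in%
                  names(gene_table)))
  membership <- tibble::as_tibble(
    gene_table[, c("genome_id", "gene_id", "family_id")])
  presence <- membership |>
    dplyr::count(.data$family_id, .data$genome_id, name = "n_genes")
  genomes <- sort(unique(membership$genome_id))
  fam_genomes <- presence |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(n_genomes = dplyr::n(),
                     multi = any(.data$n_genes > 1), .groups = "drop")
  structure(
    list(
      membership = membership,
      presence = presence,
      genomes = genomes,
      families = fam_genomes$family_id,
      core_families =
        fam_genomes$family_id[fam_genomes$n_genomes == length(genomes)],
      inconsistent_families = fam_genomes$family_id[fam_genomes$multi]
    ),
    class = "pangenome_profile"
  )
}

#' @export
print.pangenome_profile <- function(x, ...) {
  cat(sprintf(
    "<pangenome_profile> %d genomes, %d families (%d core, %d flagged)\n",
    length(x$genomes), length(x$families), length(x$core_families),
    length(x$inconsistent_families)))
  invisible(x)
}

#' Binary presence/absence matrix of a pan-genome profile
#'
#' @param profile A [pangenome_profile()].
#' @return Logical matrix, families as rows, genomes as columns.
#' @export
presence_matrix <- function(profile) {
  wide <- profile$presence |>
    dplyr::mutate(present = .data$n_genes > 0) |>
    tidyr::pivot_wider(id_cols = "family_id", names_from = "genome_id",
                       values_from = "present", values_fill = FALSE)
  m <- as.matrix(wide[, profile$genomes, drop = FALSE])
  rownames(m) <- wide$family_id
  m
}

#' Build gene families from pairwise orthology maps
#'
#' Families are the connected components of the union graph of all
#' pairwise one-to-one mappings. A component holding more than one gene
#' from a single genome (a transitivity conflict) is kept but flagged in
#' the resulting profile.
#'
#' @param maps List of [orthology_map()] objects covering the genome pairs.
#' @param gene_table Tibble with `genome_id` and `gene_id` for every gene
#'   of every genome (unmapped genes become singleton families).
#' @return A [pangenome_profile()]; the membership carries the assigned
#'   `family_id` (`FAM...`).
#' @export
build_families <- function(maps, gene_table) {
  key <- function(genome, gene) paste(genome, gene, sep = "\x1f")
  vertices <- key(gene_table$genome_id, gene_table$gene_id)
  stopifnot(!anyDuplicated(vertices))
  edges <- dplyr::bind_rows(lapply(maps, function(m) {
    tibble::tibble(
      from = key(attr(m, "genome_a"), m$gene_a),
      to = key(attr(m, "genome_b"), m$gene_b)
    )
  }))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE, vertices = data.frame(name = vertices))
  comp <- igraph::components(g)$membership
  out <- gene_table
  out$family_id <- sprintf("FAM%06d", as.integer(comp[vertices]))
  pangenome_profile(out)
}

#' Pan/core-genome rarefaction
#'
#' For each subset size `n`, draws `iterations` random `n`-subsets of the
#' genomes (without replacement within a subset, independent across
#' iterations) and records the core size (families present in all `n`)
#' and pan size (families present in at least one).
#'
#' @param profile A [pangenome_profile()].
#' @param n_range Integer vector of subset sizes (default `2:N`).
#' @param iterations Random subsets per size (default 100).
#' @param seed Integer seed.
#' @return Tibble: `n`, `iteration`, `core_size`, `pan_size`.
#' @export
rarefaction <- function(profile, n_range = NULL, iterations = 100L,
                        seed = 1L) {
  m <- presence_matrix(profile)
  genomes <- profile$genomes
  N <- length(genomes)
  if (is.null(n_range)) n_range <- 2:N
  if (any(n_range < 1 | n_range > N)) stop("n_range outside 1..", N)
  withr::with_seed(as.integer(seed), {
    recs <- lapply(n_range, function(n) {
      core <- integer(iterations)
      pan <- integer(iterations)
      for (it in seq_len(iterations)) {
        s <- sample.int(N, n)
        rs <- rowSums(m[, s, drop = FALSE])
        core[it] <- sum(rs == n)
        pan[it] <- sum(rs > 0)
      }
      tibble::tibble(n = n, iteration = seq_len(iterations),
                     core_size = core, pan_size = pan)
    })
    dplyr::bind_rows(recs)
  })
}

#' Fit Heap's law to pan-genome growth
#'
#' Least-squares fit of `log(pan) = log(kappa) + gamma * log(n)`; a
#' positive `gamma` indicates an open pan-genome.
#'
#' @param data Tibble with columns `n` and `pan` (e.g. per-`n` medians of
#'   a [rarefaction()] table), or a numeric vector `pan` with `n` supplied
#'   separately.
#' @param n Subset sizes when `data` is a bare numeric vector.
#' @return A list of class `heaps_fit`: `kappa`, `gamma`, `model` (the
#'   underlying `lm`), `n_points`.
#' @export
heaps_fit <- function(data, n = NULL) {
  if (is.numeric(data) && is.null(dim(data))) {
    data <- tibble::tibble(n = n, pan = data)
  }
  stopifnot(all(c("n", "pan") %in% names(data)))
  if (nrow(data) < 3) stop("need at least 3 points to fit Heap's law")
  if (any(data$pan <= 0) || any(data$n <= 0)) {
    stop("Heap's-law fit needs positive sizes")
  }
  fit <- stats::lm(log(pan) ~ log(n), data = data)
  structure(
    list(
      kappa = unname(exp(stats::coef(fit)[1])),
      gamma = unname(stats::coef(fit)[2]),
      model = fit, n_points = nrow(data)
    ),
    class = "heaps_fit"
  )
}

#' @export
print.heaps_fit <- function(x, ...) {
  cat(sprintf("Heap's law fit: pan(n) ~ %.4g * n^%.4g  (%d points)\n",
              x$kappa, x$gamma, x$n_points))
  invisible(x)
}

#' @rdname heaps_fit
#' @param x A `heaps_fit` object.
#' @param ... Unused.
#' @export
tidy.heaps_fit <- function(x, ...) {
  tibble::tibble(term = c("kappa", "gamma"),
                 estimate = c(x$kappa, x$gamma))
}

#' @rdname heaps_fit
#' @export
glance.heaps_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(kappa = x$kappa, gamma = x$gamma,
                 r.squared = s$r.squared, n_points = x$n_points)
}

#' Delimit the core-region of a chromosome
#'
#' The core-region is the shortest contiguous rank interval containing at
#' least `ceiling(fraction * C)` of the chromosome's `C` core genes (95 %
#' by default, to avoid overestimating its extent). Ties on span are
#' broken toward the interval whose midpoint is most central. The flanking
#' regions are the chromosomal arms.
#'
#' @param chrom A [linear_chromosome()].
#' @param is_core Logical vector, one entry per gene row of `chrom`.
#' @param fraction Fraction of core genes the region must contain.
#' @return One-row tibble: `genome_id`, `start_rank`, `end_rank`,
#'   `start_bp`, `end_bp`, `n_core_in`, `left_arm_bp`, `right_arm_bp`,
#'   `class` (`"typical"` or `"unbalanced"`).
#' @export
core_region <- function(chrom, is_core, fraction = 0.95) {
  stopifnot(length(is_core) == nrow(chrom))
  core_ranks <- chrom$rank[is_core]
  C <- length(core_ranks)
  if (C == 0) stop("no core genes on chromosome ", chrom_genome_id(chrom))
  k <- ceiling(fraction * C)
  core_ranks <- sort(core_ranks)
  n <- nrow(chrom)
  centre <- (n - 1) / 2
  best <- NULL
  for (i in seq_len(C - k + 1L)) {
    s <- core_ranks[i]
    e <- core_ranks[i + k - 1L]
    span <- e - s
    mid_off <- abs((s + e) / 2 - centre)
    if (is.null(best) || span < best$span ||
        (span == best$span && mid_off < best$mid_off)) {
      best <- list(s = s, e = e, span = span, mid_off = mid_off)
    }
  }
  start_bp <- chrom$start[chrom$rank == best$s]
  end_bp <- chrom$end[chrom$rank == best$e]
  left <- start_bp - 1L
  right <- chrom_length(chrom) - end_bp
  tibble::tibble(
    genome_id = chrom_genome_id(chrom),
    start_rank = best$s, end_rank = best$e,
    start_bp = start_bp, end_bp = end_bp,
    n_core_in = sum(core_ranks >= best$s & core_ranks <= best$e),
    left_arm_bp = left, right_arm_bp = right,
    class = classify_architecture(left, right)
  )
}

#' Classify chromosome architecture from arm sizes
#'
#' A chromosome is `"unbalanced"` when one arm is at least twice as long
#' as the other (a zero-length arm opposite a non-zero arm counts as
#' unbalanced); otherwise `"typical"`.
#'
#' @param left_arm_bp,right_arm_bp Arm sizes in bp (vectorized).
#' @return Character vector of `"typical"` / `"unbalanced"`.
#' @export
classify_architecture <- function(left_arm_bp, right_arm_bp) {
  lo <- pmin(left_arm_bp, right_arm_bp)
  hi <- pmax(left_arm_bp, right_arm_bp)
  ifelse(hi == 0, "typical",
         ifelse(lo == 0 | hi / lo >= 2, "unbalanced", "typical"))
}
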