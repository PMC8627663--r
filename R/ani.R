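# Fragment-based average nucleotide identity (ANIb), species-level
# dereplication, and terminal inverted repeat handling.

#' Fragment a genome into 1000 consecutive pieces
#'
#' The query genome of an ANIb comparison is cut into 1000 contiguous,
#' non-overlapping fragments covering the whole sequence. Fragment lengths
#' differ by at most 1 bp: the `length %% 1000` remainder bases are
#' distributed one each over the last fragments.
#'
#' @param seq Genome sequence (single character string, length >= 1000).
#' @param n_fragments Number of fragments (default 1000).
#' @return A tibble: `fragment_id`, `start`, `end`, `length`, `seq`.
#' @export
fragment_genome <- function(seq, n_fragments = 1000L) {
  seq <- as.character(seq)
  n <- nchar(seq)
  if (n < n_fragments) {
    stop("sequence length (", n, ") shorter than ", n_fragments)
  }
  base <- n %/% n_fragments
  r <- n %% n_fragments
  sizes <- rep(base, n_fragments)
  if (r > 0) sizes[seq.int(n_fragments - r + 1L, n_fragments)] <- base + 1L
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  tibble::tibble(
    fragment_id = sprintf("frag_%04d", seq_len(n_fragments)),
    start = starts, end = ends, length = sizes,
    seq = substring(seq, starts, ends)
  )
}

#' One-way ANIb score from fragment hits
#'
#' The one-way score is the mean percent identity of the best hit
#' (by bitscore) of each query fragment, over fragments whose best hit
#' aligns more than 70 % of the fragment length with at least 30 %
#' nucleotide identity. Fragments with no qualifying hit are excluded from
#' the mean; if no fragment qualifies the score is `NA` (undefined), never
#' 0.
#'
#' @param fragments Tibble from [fragment_genome()].
#' @param hits Similarity hits with `query_id` matching `fragment_id`
#'   (see [read_blast_tab()]).
#' @param min_cov Minimum alignment length as a fraction of the fragment
#'   length, exclusive (default 0.7).
#' @param min_identity Minimum percent identity of the best hit (default 30).
#' @return A single numeric percent (or `NA_real_`).
#' @export
anib_oneway <- function(fragments, hits, min_cov = 0.7, min_identity = 30) {
  if (nrow(hits) == 0) return(NA_real_)
  best <- hits |>
    dplyr::arrange(
      .data$query_id, dplyr::desc(.data$bitscore),
      dplyr::desc(.data$pct_identity), .data$subject_id
    ) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE) |>
    dplyr::inner_join(
      fragments[, c("fragment_id", "length")],
      by = c(query_id = "fragment_id")
    ) |>
    dplyr::filter(
      .data$aln_length > min_cov * .data$length,
      .data$pct_identity >= min_identity
    )
  if (nrow(best) == 0) return(NA_real_)
  mean(best$pct_identity)
}

#' Nucleotide aligner backed by blastn
#'
#' Returns a function mapping (query FASTA, subject FASTA) to a hit tibble
#' in the outfmt-6 dialect, using `makeblastdb` + `blastn`. Any callable
#' with the same contract can be injected into [anib_pair()] instead.
#'
#' @param evalue E-value cutoff passed to blastn.
#' @return A `function(query_path, subject_path)` returning a hit tibble.
#' @export
blast_aligner <- function(evalue = 1e-5) {
  if (Sys.which("blastn") == "" || Sys.which("makeblastdb") == "") {
    stop("blastn/makeblastdb not found on PATH")
  }
  function(query_path, subject_path) {
    db <- tempfile("blastdb_")
    out <- tempfile("blastout_", fileext = ".tsv")
    system2("makeblastdb",
            c("-in", subject_path, "-dbtype", "nucl", "-out", db),
            stdout = FALSE, stderr = FALSE)
    system2("blastn",
            c("-query", query_path, "-db", db, "-outfmt", "6",
              "-dust", "no", "-evalue", format(evalue), "-out", out),
            stdout = FALSE, stderr = FALSE)
    on.exit(unlink(c(out, paste0(db, ".*"))), add = TRUE)
    read_blast_tab(out)
  }
}

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

anib_oneway_seqs <- function(query_seq, subject_seq, subject_id, aligner) {
  frags <- fragment_genome(query_seq)
  qp <- tempfile("frags_", fileext = ".fna")
  sp <- tempfile("subject_", fileext = ".fna")
  on.exit(unlink(c(qp, sp)), add = TRUE)
  write_fasta(stats::setNames(frags$seq, frags$fragment_id), qp)
  write_fasta(stats::setNames(subject_seq, subject_id), sp)
  anib_oneway(frags, aligner(qp, sp))
}

#' Pairwise ANIb score
#'
#' ANIb is not reciprocal; the final score is the mean of the two one-way
#' scores (A fragmented against B, and B fragmented against A).
#'
#' @param seq_a,seq_b Genome sequences (character strings).
#' @param genome_a,genome_b Genome identifiers for the output row.
#' @param aligner An aligner function, e.g. [blast_aligner()].
#' @return One-row tibble: `genome_a`, `genome_b`, `oneway_ab`,
#'   `oneway_ba`, `final`.
#' @export
anib_pair <- function(seq_a, seq_b, genome_a = "a", genome_b = "b",
                      aligner = blast_aligner()) {
  ab <- anib_oneway_seqs(seq_a, seq_b, genome_b, aligner)
  ba <- anib_oneway_seqs(seq_b, seq_a, genome_a, aligner)
  tibble::tibble(
    genome_a = genome_a, genome_b = genome_b,
    oneway_ab = ab, oneway_ba = ba, final = (ab + ba) / 2
  )
}

#' All-pairs ANIb table
#'
#' @param genomes Named character vector of genome sequences.
#' @inheritParams anib_pair
#' @return Tibble of one row per unordered pair (see [anib_pair()]).
#' @export
anib_matrix <- function(genomes, aligner = blast_aligner()) {
  ids <- names(genomes)
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  dplyr::bind_rows(lapply(pairs, function(p) {
    anib_pair(genomes[[p[1]]], genomes[[p[2]]], p[1], p[2], aligner)
  }))
}

#' Single-linkage species clustering on an ANI table
#'
#' Genomes sharing an ANI greater than or equal to the threshold are
#' placed in the same species cluster (single linkage over the
#' >= threshold relation, i.e. connected components). The representative
#' of each cluster is its largest genome.
#'
#' @param ani Tibble with `genome_a`, `genome_b`, `final` (one row per
#'   pair; both orders accepted), or a symmetric matrix with genome ids as
#'   dimnames.
#' @param threshold Percent ANI at or above which two genomes are
#'   conspecific (default 96).
#' @param genome_sizes Optional named numeric vector used to pick the
#'   representative; falls back to alphabetical order.
#' @return Tibble: `genome_id`, `cluster` (integer), `representative`
#'   (logical).
#' @export
cluster_species <- function(ani, threshold = 96, genome_sizes = NULL) {
  if (is.matrix(ani)) {
    ids <- rownames(ani)
    idx <- which(upper.tri(ani), arr.ind = TRUE)
    ani <- tibble::tibble(
      genome_a = ids[idx[, 1]], genome_b = ids[idx[, 2]],
      final = ani[idx]
    )
  }
  ids <- sort(unique(c(ani$genome_a, ani$genome_b)))
  keep <- ani[!is.na(ani$final) & ani$final >= threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    keep[, c("genome_a", "genome_b")], directed = FALSE,
    vertices = data.frame(name = ids)
  )
  comp <- igraph::components(g)$membership
  out <- tibble::tibble(genome_id = names(comp),
                        cluster = as.integer(comp))
  size_of <- function(id) {
    if (is.null(genome_sizes)) 0 else as.numeric(genome_sizes[[id]])
  }
  out <- out |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(
      representative = .data$genome_id ==
        .data$genome_id[order(-vapply(.data$genome_id, size_of, 0),
                              .data$genome_id)][1]
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$cluster, .data$genome_id)
  out
}

#' Detect terminal inverted repeats
#'
#' Scans for the longest prefix that matches the reverse complement of the
#' equal-length suffix at or above `min_identity` percent identity, with a
#' minimum length of `min_len`; the repeat must end on a matching base.
#' Returns length 0 when no terminal repeat qualifies.
#'
#' @param seq Genome sequence (character string).
#' @param min_len Minimum repeat length in bp (default 50).
#' @param min_identity Minimum percent identity (default 99).
#' @param genome_id Optional id carried into the output.
#' @return One-row tibble: `genome_id`, `tir_length_bp`, `pct_identity`.
#' @export
detect_tir <- function(seq, min_len = 50L, min_identity = 99,
                       genome_id = NA_character_) {
  seq <- as.character(seq)
  n <- nchar(seq)
  half <- n %/% 2L
  out0 <- tibble::tibble(genome_id = genome_id, tir_length_bp = 0L,
                         pct_identity = NA_real_)
  if (half < min_len) return(out0)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  m <- chars[seq_len(half)] == comp_base(chars[seq.int(n, n - half + 1L)])
  ident <- cumsum(m) / seq_len(half)
  ok <- m & ident >= min_identity / 100 & seq_len(half) >= min_len
  if (!any(ok)) return(out0)
  L <- max(which(ok))
  tibble::tibble(genome_id = genome_id, tir_length_bp = L,
                 pct_identity = 100 * ident[L])
}

#' Trim a terminal inverted repeat to a single copy
#'
#' Removes the right-hand copy of the repeat (the last `tir_length_bp`
#' bases). When a gene table is supplied, genes lying entirely within the
#' removed copy are dropped; a gene straddling the trim boundary is
#' truncated out with a warning.
#'
#' @param seq Genome sequence (character string).
#' @param tir_length_bp Repeat length, e.g. from [detect_tir()]; must be
#'   less than half the sequence length.
#' @param chrom Optional [linear_chromosome()] on the same sequence.
#' @return The trimmed sequence, or when `chrom` is given a list with
#'   elements `seq` and `chromosome`.
#' @export
trim_tir <- function(seq, tir_length_bp, chrom = NULL) {
  seq <- as.character(seq)
  n <- nchar(seq)
  tir_length_bp <- as.integer(tir_length_bp)
  stopifnot(tir_length_bp >= 0, tir_length_bp < n / 2)
  new_n <- n - tir_length_bp
  trimmed <- substr(seq, 1L, new_n)
  if (is.null(chrom)) return(trimmed)
  straddle <- chrom$start <= new_n & chrom$end > new_n
  if (any(straddle)) {
    warning(sum(straddle), " gene(s) straddle the trim boundary; dropped")
  }
  keep <- chrom$end <= new_n
  new_chrom <- linear_chromosome(
    tibble::as_tibble(chrom)[keep, , drop = FALSE],
    genome_id = chrom_genome_id(chrom),
    length_bp = new_n, tir_length_bp = 0L
  )
  list(seq = trimmed, chromosome = new_chrom)
}
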