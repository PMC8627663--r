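# Reciprocal-best-hit orthology and protein similarity searches.

#' Construct an orthology map
#'
#' A one-to-one gene mapping between two genomes. Used both for maps
#' inferred by [bbh_orthologs()] and for simulator ground truth
#' ([truth_orthology()]).
#'
#' @param tbl Tibble with columns `gene_a`, `gene_b` (extra columns kept).
#' @param genome_a,genome_b Genome identifiers.
#' @return Tibble of class `orthology_map` with attributes `genome_a`,
#'   `genome_b`.
#' @export
orthology_map <- function(tbl, genome_a, genome_b) {
  tbl <- tibble::as_tibble(tbl)
  stopifnot(all(c("gene_a", "gene_b") %in% names(tbl)))
  if (anyDuplicated(tbl$gene_a) || anyDuplicated(tbl$gene_b)) {
    stop("orthology map must be one-to-one")
  }
  structure(tbl, genome_a = genome_a, genome_b = genome_b,
            class = c("orthology_map", class(tibble::tibble())))
}

# Best hit per query: highest bitscore, ties broken by higher identity,
# then lexicographic subject id (determinism under input permutation).
best_hits <- function(hits) {
  hits |>
    dplyr::arrange(
      .data$query_id, dplyr::desc(.data$bitscore),
      dplyr::desc(.data$pct_identity), .data$subject_id
    ) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
}

#' Reciprocal-best-hit orthologues between two proteomes
#'
#' A pair (x, y) is orthologous when y is x's best hit, x is y's best hit,
#' and in both directions the hit shows at least `min_identity` percent
#' identity, at least `min_cov` percent coverage of both query and
#' subject, and an E-value lower than `max_evalue`. Best = maximal
#' bitscore, ties broken by identity then subject id.
#'
#' @param hits_ab,hits_ba Similarity hit tibbles (a vs b and b vs a) with
#'   `q_cov`/`s_cov` columns (see [add_hit_coverage()]).
#' @param min_identity Percent identity floor (default 40).
#' @param min_cov Percent coverage floor, applied to query and subject
#'   (default 70).
#' @param max_evalue Exclusive E-value ceiling (default 1e-10).
#' @param genome_a,genome_b Genome ids for the returned map.
#' @return An [orthology_map()] with columns `gene_a`, `gene_b`,
#'   `pct_identity` (a-vs-b direction).
#' @export
bbh_orthologs <- function(hits_ab, hits_ba, min_identity = 40,
                          min_cov = 70, max_evalue = 1e-10,
                          genome_a = "a", genome_b = "b") {
  gate <- function(h) {
    if (!all(c("q_cov", "s_cov") %in% names(h))) {
      stop("hits need q_cov and s_cov columns; see add_hit_coverage()")
    }
    dplyr::filter(
      h,
      .data$pct_identity >= min_identity,
      .data$q_cov >= min_cov, .data$s_cov >= min_cov,
      .data$evalue < max_evalue
    )
  }
  ab <- best_hits(gate(hits_ab))
  ba <- best_hits(gate(hits_ba))
  m <- dplyr::inner_join(
    tibble::tibble(gene_a = ab$query_id, gene_b = ab$subject_id,
                   pct_identity = ab$pct_identity),
    tibble::tibble(gene_b = ba$query_id, gene_a = ba$subject_id),
    by = c("gene_a", "gene_b")
  )
  orthology_map(m, genome_a, genome_b)
}

#' Protein similarity hits via blastp
#'
#' Runs blastp between two sets of protein sequences and attaches query
#' and subject coverage, yielding hits ready for [bbh_orthologs()].
#'
#' @param query_seqs,subject_seqs Named character vectors of amino-acid
#'   sequences.
#' @param evalue E-value cutoff passed to blastp.
#' @return A hit tibble with `q_cov`/`s_cov` columns.
#' @export
blastp_hits <- function(query_seqs, subject_seqs, evalue = 1e-3) {
  if (Sys.which("blastp") == "" || Sys.which("makeblastdb") == "") {
    stop("blastp/makeblastdb not found on PATH")
  }
  qp <- tempfile("query_", fileext = ".faa")
  sp <- tempfile("subject_", fileext = ".faa")
  db <- tempfile("blastdb_")
  out <- tempfile("blastout_", fileext = ".tsv")
  on.exit(unlink(c(qp, sp, out, paste0(db, ".*"))), add = TRUE)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(query_seqs), qp)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(subject_seqs), sp)
  system2("makeblastdb", c("-in", sp, "-dbtype", "prot", "-out", db),
          stdout = FALSE, stderr = FALSE)
  system2("blastp", c("-query", qp, "-db", db, "-outfmt", "6",
                      "-evalue", format(evalue), "-out", out),
          stdout = FALSE, stderr = FALSE)
  hits <- read_blast_tab(out)
  add_hit_coverage(hits, nchar(query_seqs), nchar(subject_seqs))
}
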