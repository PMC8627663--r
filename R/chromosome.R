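#' Build a linear chromosome gene table
#'
#' The central container of the package: an ordered, stranded gene list on a
#' single linear replicon, held as a tibble with one row per gene. Genes are
#' sorted by start coordinate and assigned a 0-based `rank` (left telomere
#' first). Coordinates are 1-based inclusive (GFF3 convention).
#'
#' @param genes Data frame with columns `gene_id`, `start`, `end`, `strand`
#'   and optionally `family_id` and `protein_seq`.
#' @param genome_id Genome identifier stored on every row.
#' @param length_bp Replicon length in bp; defaults to `max(end)`.
#' @param tir_length_bp Length of the terminal inverted repeat, if known.
#' @return A tibble of class `linear_chromosome` with columns `gene_id`,
#'   `genome_id`, `rank`, `start`, `end`, `strand` (+ optional columns),
#'   and attributes `genome_id`, `length_bp`, `tir_length_bp`.
#' @export
linear_chromosome <- function(genes, genome_id, length_bp = NULL,
                              tir_length_bp = 0L) {
  genes <- tibble::as_tibble(genes)
  required <- c("gene_id", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    stop("gene table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  genes$gene_id <- as.character(genes$gene_id)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- as.character(genes$strand)

  if (nrow(genes) > 0) {
    if (anyDuplicated(genes$gene_id)) {
      stop("duplicate gene_id in genome '", genome_id, "'")
    }
    if (any(genes$start > genes$end)) stop("start > end for some gene(s)")
    if (any(genes$start < 1)) stop("start < 1 for some gene(s)")
    bad <- setdiff(unique(genes$strand), c("+", "-"))
    if (length(bad) > 0) {
      stop("unknown strand symbol(s): ", paste(bad, collapse = ", "))
    }
  }
  genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  genes$rank <- if (nrow(genes) > 0) seq_len(nrow(genes)) - 1L else integer(0)
  genes$genome_id <- rep(as.character(genome_id), nrow(genes))
  keep <- intersect(
    c("gene_id", "genome_id", "rank", "start", "end", "strand",
      "family_id", "protein_seq"),
    names(genes)
  )
  genes <- genes[, keep, drop = FALSE]

  if (is.null(length_bp)) {
    length_bp <- if (nrow(genes) > 0) max(genes$end) else 0L
  }
  length_bp <- as.integer(length_bp)
  tir_length_bp <- as.integer(tir_length_bp)
  if (nrow(genes) > 0 && max(genes$end) > length_bp) {
    stop("gene coordinates exceed length_bp")
  }
  if (tir_length_bp < 0 || (length_bp > 0 && tir_length_bp > length_bp / 2)) {
    stop("tir_length_bp must lie in [0, length_bp/2]")
  }

  structure(
    genes,
    genome_id = as.character(genome_id),
    length_bp = length_bp,
    tir_length_bp = tir_length_bp,
    class = c("linear_chromosome", class(tibble::tibble()))
  )
}

#' @export
print.linear_chromosome <- function(x, ...) {
  cat(sprintf(
    "<linear_chromosome> %s: %d genes, %s bp, TIR %s bp\n",
    attr(x, "genome_id"), nrow(x),
    format(attr(x, "length_bp"), big.mark = ","),
    format(attr(x, "tir_length_bp"), big.mark = ",")
  ))
  NextMethod()
}

#' Chromosome metadata accessors
#'
#' @param chrom A `linear_chromosome`.
#' @return `chrom_length()` the replicon length in bp; `chrom_genome_id()`
#'   the genome identifier; `n_genes()` the gene count.
#' @export
chrom_length <- function(chrom) attr(chrom, "length_bp")

#' @rdname chrom_length
#' @export
chrom_genome_id <- function(chrom) attr(chrom, "genome_id")

#' @rdname chrom_length
#' @export
n_genes <- function(chrom) nrow(chrom)

#' Read a gene table from TSV or GFF3
#'
#' TSV tables are tab-separated with a header line
#' (`gene_id`, `start`, `end`, `strand`, optionally `family_id`), `#` comment
#' lines skipped. GFF3 input (detected from the file extension or a
#' `##gff-version` pragma) is restricted to CDS features on one sequence
#' region, with the feature `ID` used as `gene_id`.
#'
#' @inheritParams linear_chromosome
#' @param path Path to the file.
#' @return A [linear_chromosome()].
#' @export
read_gene_table <- function(path, genome_id, length_bp = NULL,
                            tir_length_bp = 0L) {
  first <- readLines(path, n = 1L)
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE) ||
    (length(first) == 1 && startsWith(first, "##gff-version"))
  if (is_gff) {
    gff <- rtracklayer::readGFF(path)
    gff <- as.data.frame(gff)
    gff <- gff[gff$type == "CDS", , drop = FALSE]
    if (nrow(gff) > 0 && length(unique(gff$seqid)) > 1) {
      stop("GFF3 contains more than one sequence region")
    }
    ids <- if ("ID" %in% names(gff)) as.character(gff$ID) else NA_character_
    if (nrow(gff) > 0 && (all(is.na(ids)) || any(is.na(ids)))) {
      ids <- paste0(genome_id, "_cds", seq_len(nrow(gff)))
    }
    genes <- tibble::tibble(
      gene_id = ids,
      start = as.integer(gff$start),
      end = as.integer(gff$end),
      strand = as.character(gff$strand)
    )
  } else {
    genes <- readr::read_tsv(
      path, comment = "#", show_col_types = FALSE, progress = FALSE,
      col_types = readr::cols(
        gene_id = readr::col_character(),
        start = readr::col_integer(),
        end = readr::col_integer(),
        strand = readr::col_character(),
        .default = readr::col_character()
      )
    )
  }
  linear_chromosome(genes, genome_id = genome_id, length_bp = length_bp,
                    tir_length_bp = tir_length_bp)
}

#' Write a gene table as TSV
#'
#' Round-trips through [read_gene_table()]: gene identifiers, ranks,
#' coordinates and strands are preserved exactly.
#'
#' @param chrom A `linear_chromosome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(chrom, path) {
  cols <- intersect(c("gene_id", "start", "end", "strand", "family_id"),
                    names(chrom))
  readr::write_tsv(as.data.frame(chrom)[, cols, drop = FALSE], path,
                   progress = FALSE)
  invisible(path)
}

#' Read BLAST tabular (outfmt 6) similarity hits
#'
#' Parses the 12-column BLAST `-outfmt 6` dialect
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore), optionally extended with a 13th `qcovs` column.
#' Multiple hits per query are preserved in file order.
#'
#' @param path Path to a BLAST tabular file.
#' @return A tibble with one row per hit: `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `mismatch`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore` and, when present, `q_cov`.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  empty <- tibble::tibble(
    query_id = character(0), subject_id = character(0),
    pct_identity = numeric(0), aln_length = integer(0),
    mismatch = integer(0), gapopen = integer(0),
    qstart = integer(0), qend = integer(0),
    sstart = integer(0), send = integer(0),
    evalue = numeric(0), bitscore = numeric(0)
  )
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 12)) {
    stop("BLAST tabular row with fewer than 12 columns (row ",
         which(ncols < 12)[1], ")")
  }
  m <- do.call(rbind, lapply(fields, function(f) f[1:12]))
  pid <- suppressWarnings(as.numeric(m[, 3]))
  if (any(is.na(pid))) stop("non-numeric identity in BLAST tabular input")
  hits <- tibble::tibble(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = pid,
    aln_length = as.integer(m[, 4]),
    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12])
  )
  if (all(ncols >= 13)) hits$q_cov <- as.numeric(vapply(fields, `[[`, "", 13))
  hits
}

#' Attach query/subject coverage to similarity hits
#'
#' Coverage is the fraction of the sequence length spanned by the aligned
#' interval, as a percentage. Needed by the reciprocal-best-hit filter,
#' which gates on both query and subject coverage.
#'
#' @param hits Tibble from [read_blast_tab()] (or same columns).
#' @param query_lengths,subject_lengths Named integer vectors of sequence
#'   lengths, keyed by sequence id.
#' @return `hits` with numeric columns `q_cov` and `s_cov` (percent).
#' @export
add_hit_coverage <- function(hits, query_lengths, subject_lengths) {
  hits$q_cov <- 100 * (abs(hits$qend - hits$qstart) + 1) /
    as.numeric(query_lengths[hits$query_id])
  hits$s_cov <- 100 * (abs(hits$send - hits$sstart) + 1) /
    as.numeric(subject_lengths[hits$subject_id])
  hits
}

#' Read a phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()] with the validation downstream analyses rely
#' on: unique leaf labels and branch lengths present (a tree without branch
#' lengths is accepted with a warning, all lengths set to 0).
#'
#' @param path Path to a single-tree Newick file.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label(s) in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; treating all as 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  tree
}
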