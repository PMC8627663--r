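# Sequence emission for simulated truth sets: ancestral family sequences
# evolve by point substitution along the tree; genomes are gene + spacer
# concatenations with terminal inverted repeats planted at both ends.

STOP_CODONS <- c("TAA", "TAG", "TGA")
DNA_BASES <- c("A", "C", "G", "T")

comp_base <- function(x) chartr("ACGT", "TGCA", x)

revcomp_chars <- function(x) rev(comp_base(x))

# Random coding sequence as a base vector, free of in-frame stop codons.
random_cds <- function(n_codons) {
  codons <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cd <- paste(sample(DNA_BASES, 3L, replace = TRUE), collapse = "")
      if (!cd %in% STOP_CODONS) break
    }
    codons[i] <- cd
  }
  strsplit(paste(codons, collapse = ""), "", fixed = TRUE)[[1]]
}

# Point substitutions at per-site probability p, keeping the frame stop-free.
mutate_cds <- function(bases, p) {
  n <- length(bases)
  k <- stats::rbinom(1L, n, min(1, p))
  if (k == 0) return(bases)
  pos <- sample.int(n, k)
  for (i in pos) {
    cod_start <- ((i - 1L) %/% 3L) * 3L + 1L
    alts <- sample(setdiff(DNA_BASES, bases[i]))
    for (b in alts) {
      cand <- bases
      cand[i] <- b
      cd <- paste(cand[cod_start:(cod_start + 2L)], collapse = "")
      if (!cd %in% STOP_CODONS) {
        bases <- cand
        break
      }
    }
  }
  bases
}

translate_cds <- function(bases) {
  as.character(Biostrings::translate(
    Biostrings::DNAString(paste(bases, collapse = "")),
    no.init.codon = TRUE
  ))
}

#' Emit nucleotide and protein sequences for a simulated truth set
#'
#' Each gene family gets a random ancestral coding sequence (no in-frame
#' stops); sequences accumulate point substitutions along every branch at
#' `params$subst_rate` per site per unit branch length. A leaf genome is
#' the concatenation of a fixed spacer and its genes' sequences (reverse
#' complemented on the minus strand), matching the coordinates of the
#' leaf's gene table. When `params$tir_length_bp > 0`, the reverse
#' complement of the first `tir_length_bp` bases is appended at the right
#' end, planting a perfect terminal inverted repeat; the bases immediately
#' inside each copy are forced to diverge so that the planted length is
#' the true maximal TIR of the emitted sequence.
#'
#' @param truth A `truth_set` from [evolve_tree()].
#' @param params The [evolution_params()] used to generate it.
#' @param dir Optional output directory; when given, writes per-leaf genome
#'   FASTA (`<leaf>.fna`), protein FASTA (`<leaf>.faa`), gene-table TSV,
#'   the event log and the Newick tree.
#' @return A list: `genomes` (named character vector of genome sequences),
#'   `proteins` (named list of named amino-acid vectors, keyed by gene id),
#'   `chromosomes` (gene tables with `length_bp`/`tir_length_bp` updated
#'   for the planted TIR).
#' @export
emit_sequences <- function(truth, params, dir = NULL) {
  tree <- truth$tree
  n_tip <- length(tree$tip.label)
  fams <- sort(unique(c(
    truth$ancestor$family_id,
    unlist(lapply(truth$chromosomes, function(ch) ch$family_id))
  )))
  n_codons <- params$gene_length_bp %/% 3L

  root_seqs <- withr::with_seed(branch_seed(params$seed, "seq:root"), {
    stats::setNames(lapply(fams, function(f) random_cds(n_codons)), fams)
  })
  spacer <- withr::with_seed(branch_seed(params$seed, "seq:spacer"), {
    sample(DNA_BASES, params$spacer_bp, replace = TRUE)
  })

  node_label <- function(v) {
    if (v <= n_tip) tree$tip.label[v] else paste0("node", v)
  }
  children <- split(tree$edge[, 2], tree$edge[, 1])
  edge_len <- stats::setNames(tree$edge.length, tree$edge[, 2])

  leaf_seqs <- list()
  recurse <- function(v, seqs) {
    kids <- children[[as.character(v)]]
    if (is.null(kids)) {
      leaf_seqs[[node_label(v)]] <<- seqs
      return(invisible())
    }
    for (k in kids) {
      lab <- node_label(k)
      p <- params$subst_rate * edge_len[[as.character(k)]]
      st <- withr::with_seed(branch_seed(params$seed, paste0("seq:", lab)), {
        if (p > 0) lapply(seqs, mutate_cds, p = p) else seqs
      })
      recurse(k, st)
    }
  }
  recurse(n_tip + 1L, root_seqs)

  genomes <- character(0)
  proteins <- list()
  chroms_out <- list()
  for (leaf in names(truth$chromosomes)) {
    ch <- truth$chromosomes[[leaf]]
    seqs <- leaf_seqs[[leaf]]
    parts <- vector("list", 2L * nrow(ch) + 1L)
    parts[[1]] <- spacer
    for (i in seq_len(nrow(ch))) {
      g <- seqs[[ch$family_id[i]]]
      if (ch$strand[i] == "-") g <- revcomp_chars(g)
      parts[[2L * i]] <- g
      parts[[2L * i + 1L]] <- spacer
    }
    body <- unlist(parts, use.names = FALSE)
    tir <- params$tir_length_bp
    if (tir > 0) {
      if (tir > length(body) / 2) stop("tir_length_bp exceeds half the genome")
      # divergence guard: the 20 bp inside the left copy must not extend
      # the repeat by chance
      L0 <- length(body)
      guard <- seq_len(min(20L, L0 - tir))
      body[tir + guard] <- withr::with_seed(
        branch_seed(params$seed, paste0("seq:guard:", leaf)), {
          vapply(guard, function(u) {
            sample(setdiff(DNA_BASES, comp_base(body[L0 + 1L - u])), 1L)
          }, character(1))
        })
      body <- c(body, revcomp_chars(body[seq_len(tir)]))
    }
    genomes[leaf] <- paste(body, collapse = "")
    prot <- vapply(seq_len(nrow(ch)), function(i) {
      translate_cds(seqs[[ch$family_id[i]]])
    }, character(1))
    names(prot) <- ch$gene_id
    proteins[[leaf]] <- prot
    chroms_out[[leaf]] <- linear_chromosome(
      tibble::as_tibble(ch), genome_id = leaf,
      length_bp = nchar(genomes[leaf]),
      tir_length_bp = tir
    )
  }

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (leaf in names(genomes)) {
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(stats::setNames(genomes[leaf], leaf)),
        file.path(dir, paste0(leaf, ".fna")))
      Biostrings::writeXStringSet(
        Biostrings::AAStringSet(proteins[[leaf]]),
        file.path(dir, paste0(leaf, ".faa")))
      write_gene_table(chroms_out[[leaf]],
                       file.path(dir, paste0(leaf, ".genes.tsv")))
    }
    readr::write_tsv(truth$events, file.path(dir, "events.tsv"),
                     progress = FALSE)
    ape::write.tree(tree, file.path(dir, "tree.nwk"))
  }

  list(genomes = genomes, proteins = proteins, chromosomes = chroms_out)
}
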