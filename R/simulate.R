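#' Parameters for the linear-chromosome evolution simulator
#'
#' The simulator evolves a single linear chromosome along a phylogeny under
#' a recombination gradient: inversions, gene gains (horizontal transfer)
#' and gene losses whose positional density increases towards the
#' telomeres, over a conserved central skeleton of core genes. The
#' positional weight of an event at relative rank `x` in `[0, 1]` is
#' `g(x) = (2 * |x - 0.5|)^beta`; `beta = 0` recovers a uniform
#' distribution, larger `beta` concentrates events in the chromosomal arms.
#'
#' Event counts per branch are Poisson with mean
#' `rate * branch_length * n_genes`; rates are therefore expected events
#' per gene per unit branch length.
#'
#' @param n_core Number of core (skeleton) gene families; exempt from loss.
#' @param n_accessory_init Number of ancestral accessory families.
#' @param arm_fraction Fraction of ancestral gene ranks forming each arm
#'   (in `[0, 0.5]`); arms carry only accessory genes.
#' @param rate_inversion,rate_gain,rate_loss Expected events per gene per
#'   unit branch length.
#' @param gradient_exponent Exponent `beta >= 0` of the telomere gradient.
#' @param inversion_mean_genes Mean inverted-segment length, in genes
#'   (geometric).
#' @param hgt_pool_size Number of novel families available for gain,
#'   consumed without replacement.
#' @param tir_length_bp Terminal inverted repeat length planted on emitted
#'   genome sequences.
#' @param gene_length_bp Gene length in bp (multiple of 3).
#' @param spacer_bp Intergenic spacer length in bp.
#' @param subst_rate Nucleotide substitutions per site per unit branch
#'   length applied when emitting sequences.
#' @param seed Root seed; per-branch streams are derived from it
#'   deterministically.
#' @return A list of class `evolution_params`.
#' @export
evolution_params <- function(n_core = 300, n_accessory_init = 300,
                             arm_fraction = 0.25,
                             rate_inversion = 0.1, rate_gain = 0.2,
                             rate_loss = 0.2, gradient_exponent = 3,
                             inversion_mean_genes = 5,
                             hgt_pool_size = 5000,
                             tir_length_bp = 0L, gene_length_bp = 900L,
                             spacer_bp = 100L, subst_rate = 0.02,
                             seed = 1L) {
  p <- list(
    n_core = as.integer(n_core),
    n_accessory_init = as.integer(n_accessory_init),
    arm_fraction = arm_fraction,
    rate_inversion = rate_inversion, rate_gain = rate_gain,
    rate_loss = rate_loss, gradient_exponent = gradient_exponent,
    inversion_mean_genes = inversion_mean_genes,
    hgt_pool_size = as.integer(hgt_pool_size),
    tir_length_bp = as.integer(tir_length_bp),
    gene_length_bp = as.integer(gene_length_bp),
    spacer_bp = as.integer(spacer_bp),
    subst_rate = subst_rate,
    seed = as.integer(seed)
  )
  stopifnot(
    p$n_core >= 2,
    p$arm_fraction >= 0, p$arm_fraction <= 0.5,
    p$rate_inversion >= 0, p$rate_gain >= 0, p$rate_loss >= 0,
    p$gradient_exponent >= 0,
    p$gene_length_bp %% 3 == 0
  )
  class(p) <- "evolution_params"
  p
}

# Telomere-gradient positional weight on relative rank x in [0, 1].
gradient_weight <- function(x, beta) {
  w <- (2 * abs(x - 0.5))^beta
  # keep the sampling distribution proper even when the centre gets weight 0
  w + 1e-9
}

# Deterministic 31-bit stream seed for a branch, from root seed + node label.
branch_seed <- function(root_seed, label) {
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 131 + c) %% 2147483647
  as.integer((as.numeric(root_seed) * 48271 + h) %% 2147483647)
}

#' Generate the ancestral linear chromosome
#'
#' Lays out `n_core` core families inside the central
#' `1 - 2 * arm_fraction` span of ranks, interleaved with accessory
#' families; the two arms carry only accessory families. Coordinates are
#' synthesized with fixed gene length and spacing.
#'
#' @param params An [evolution_params()] object.
#' @return A [linear_chromosome()] for genome `"ancestor"`, with
#'   `family_id` set on every gene (`CORE...` / `ACC...`).
#' @export
generate_ancestor <- function(params) {
  n <- params$n_core + params$n_accessory_init
  n_arm <- floor(params$arm_fraction * n)
  centre <- n - 2L * n_arm
  if (params$n_core > centre) {
    stop("n_core (", params$n_core, ") exceeds the ", centre,
         " central ranks allowed by arm_fraction")
  }
  fam <- withr::with_seed(params$seed, {
    core_ids <- sprintf("CORE%05d", seq_len(params$n_core))
    acc_ids <- if (params$n_accessory_init > 0) {
      sprintf("ACC%05d", seq_len(params$n_accessory_init))
    } else character(0)
    slots <- rep(NA_character_, n)
    centre_ranks <- seq.int(n_arm + 1L, n - n_arm)
    core_pos <- sort(sample(centre_ranks, params$n_core))
    slots[core_pos] <- core_ids
    slots[is.na(slots)] <- sample(acc_ids)
    tibble::tibble(
      family_id = slots,
      strand = sample(c("+", "-"), n, replace = TRUE)
    )
  })
  state_to_chromosome(fam, "ancestor", params)
}

# Convert an internal gene-order state (family_id, strand) into a
# linear_chromosome with synthesized coordinates.
state_to_chromosome <- function(state, genome_id, params) {
  n <- nrow(state)
  pitch <- params$gene_length_bp + params$spacer_bp
  start <- params$spacer_bp + (seq_len(n) - 1L) * pitch + 1L
  genes <- tibble::tibble(
    gene_id = sprintf("%s_g%05d", genome_id, seq_len(n)),
    start = as.integer(start),
    end = as.integer(start + params$gene_length_bp - 1L),
    strand = state$strand,
    family_id = state$family_id
  )
  linear_chromosome(genes, genome_id = genome_id,
                    length_bp = n * pitch + params$spacer_bp)
}

# Sample one gene index with telomere-gradient weighting.
sample_gradient_rank <- function(n, beta, candidates = seq_len(n)) {
  x <- (candidates - 0.5) / n
  w <- gradient_weight(x, beta)
  candidates[sample.int(length(candidates), 1L, prob = w)]
}

apply_inversion <- function(state, params) {
  n <- nrow(state)
  if (n < 2) return(list(state = state, pos = NA_real_, detail = "0"))
  i <- sample_gradient_rank(n, params$gradient_exponent)
  len <- min(n, stats::rgeom(1L, 1 / params$inversion_mean_genes) + 1L)
  j <- if (stats::runif(1) < 0.5) max(1L, i - len + 1L) else min(n, i + len - 1L)
  seg <- seq.int(min(i, j), max(i, j))
  state[seg, ] <- state[rev(seg), ]
  state$strand[seg] <- ifelse(state$strand[seg] == "+", "-", "+")
  list(state = state, pos = (i - 0.5) / n,
       detail = paste0(min(i, j), "-", max(i, j)))
}

apply_gain <- function(state, params, pool_env) {
  n <- nrow(state)
  # insertion slot s in 0..n, weighted by its relative position
  slots <- 0:n
  w <- gradient_weight(slots / max(n, 1L), params$gradient_exponent)
  s <- slots[sample.int(n + 1L, 1L, prob = w)]
  pool_env$next_id <- pool_env$next_id + 1L
  if (pool_env$next_id > params$hgt_pool_size) stop("HGT pool exhausted")
  fam <- sprintf("HGT%05d", pool_env$next_id)
  row <- tibble::tibble(family_id = fam,
                        strand = sample(c("+", "-"), 1L))
  state <- dplyr::bind_rows(
    if (s > 0) state[seq_len(s), ] else NULL,
    row,
    if (s < n) state[seq.int(s + 1L, n), ] else NULL
  )
  list(state = state, pos = s / max(n, 1L), detail = fam)
}

apply_loss <- function(state, params) {
  acc <- which(!startsWith(state$family_id, "CORE"))
  if (length(acc) == 0) {
    return(list(state = state, pos = NA_real_, detail = "none"))
  }
  i <- sample_gradient_rank(nrow(state), params$gradient_exponent,
                            candidates = acc)
  detail <- state$family_id[i]
  list(state = state[-i, ], pos = (i - 0.5) / nrow(state), detail = detail)
}

#' Evolve an ancestral chromosome along a phylogeny
#'
#' Walks the tree from the root; on every branch, draws Poisson numbers of
#' inversions, gains and losses (mean `rate * branch_length * n_genes`),
#' places them with telomere-gradient weighting, and applies them
#' sequentially. Core families are exempt from loss (they may be relocated
#' by inversions), so the skeleton is present exactly once in every leaf.
#'
#' @param ancestor A [generate_ancestor()] chromosome (needs `family_id`).
#' @param tree An [ape::phylo] phylogeny with branch lengths.
#' @param params An [evolution_params()] object.
#' @return A list of class `truth_set`: `chromosomes` (named list of
#'   [linear_chromosome()] per leaf), `events` (tibble: branch, type,
#'   rel_pos, detail), `tree`, `ancestor`, `params`.
#' @export
evolve_tree <- function(ancestor, tree, params) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  n_tip <- length(tree$tip.label)
  node_label <- function(v) {
    if (v <= n_tip) tree$tip.label[v]
    else if (!is.null(tree$node.label) && nzchar(tree$node.label[v - n_tip])) {
      tree$node.label[v - n_tip]
    } else paste0("node", v)
  }
  root_state <- tibble::tibble(family_id = ancestor$family_id,
                               strand = ancestor$strand)
  pool_env <- new.env(parent = emptyenv())
  pool_env$next_id <- 0L
  chromosomes <- list()
  events <- list()

  children <- split(tree$edge[, 2], tree$edge[, 1])
  edge_len <- stats::setNames(tree$edge.length, tree$edge[, 2])

  recurse <- function(v, state) {
    kids <- children[[as.character(v)]]
    if (is.null(kids)) {
      chromosomes[[node_label(v)]] <<- state_to_chromosome(
        state, node_label(v), params)
      return(invisible())
    }
    for (k in kids) {
      lab <- node_label(k)
      bl <- edge_len[[as.character(k)]]
      st <- withr::with_seed(branch_seed(params$seed, lab), {
        evolve_branch(state, bl, lab, params, pool_env,
                      function(ev) events[[length(events) + 1L]] <<- ev)
      })
      recurse(k, st)
    }
  }
  evolve_branch <- function(state, bl, lab, params, pool_env, log_fn) {
    n0 <- nrow(state)
    counts <- stats::rpois(3L, c(params$rate_inversion, params$rate_gain,
                                 params$rate_loss) * bl * n0)
    types <- rep(c("inversion", "gain", "loss"), counts)
    if (length(types) > 1) types <- sample(types)
    for (ty in types) {
      res <- switch(ty,
        inversion = apply_inversion(state, params),
        gain = apply_gain(state, params, pool_env),
        loss = apply_loss(state, params)
      )
      state <- res$state
      if (nrow(state) < params$n_core) {
        stop("chromosome on branch to '", lab,
             "' shrank below the core skeleton size")
      }
      log_fn(tibble::tibble(branch = lab, type = ty,
                            rel_pos = res$pos, detail = res$detail))
    }
    state
  }
  recurse(n_tip + 1L, root_state)

  structure(
    list(
      chromosomes = chromosomes,
      events = if (length(events)) dplyr::bind_rows(events) else
        tibble::tibble(branch = character(0), type = character(0),
                       rel_pos = numeric(0), detail = character(0)),
      tree = tree, ancestor = ancestor, params = params
    ),
    class = "truth_set"
  )
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> %d leaves, %d recorded events\n",
              length(x$chromosomes), nrow(x$events)))
  invisible(x)
}

#' Combined gene table of a simulated truth set
#'
#' @param truth A `truth_set` from [evolve_tree()].
#' @return One tibble with all leaves' gene records stacked.
#' @export
truth_gene_table <- function(truth) {
  dplyr::bind_rows(lapply(truth$chromosomes, tibble::as_tibble))
}

#' Ground-truth orthology map between two simulated genomes
#'
#' Pairs genes of the two leaves that carry the same `family_id`; since the
#' simulator keeps every family single-copy, the map is one-to-one.
#'
#' @param truth A `truth_set`.
#' @param a,b Leaf genome ids.
#' @return An orthology map tibble (`gene_a`, `gene_b`, `family_id`) with
#'   attributes `genome_a`, `genome_b`.
#' @export
truth_orthology <- function(truth, a, b) {
  ca <- truth$chromosomes[[a]]
  cb <- truth$chromosomes[[b]]
  if (is.null(ca) || is.null(cb)) stop("unknown leaf genome id")
  m <- dplyr::inner_join(
    tibble::tibble(gene_a = ca$gene_id, family_id = ca$family_id),
    tibble::tibble(gene_b = cb$gene_id, family_id = cb$family_id),
    by = "family_id"
  )
  orthology_map(m[, c("gene_a", "gene_b", "family_id")], a, b)
}

#' Simulate a coalescent-shaped ultrametric phylogeny
#'
#' A thin, seeded wrapper around [ape::rcoal()] rescaled to a chosen root
#' depth, so that cophenetic distances fall in a controlled range.
#'
#' @param n_leaves Number of leaves.
#' @param depth Root-to-tip depth after rescaling.
#' @param seed Integer seed.
#' @return An [ape::phylo] with tip labels `g01, g02, ...`.
#' @export
sim_tree <- function(n_leaves, depth = 0.3, seed = 1L) {
  tree <- withr::with_seed(as.integer(seed), ape::rcoal(n_leaves))
  tree$tip.label <- sprintf("g%02d", seq_len(n_leaves))
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * depth / h
  tree
}
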