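# Double-cut-and-join (DCJ) rearrangement distance on shared markers.
#
# A signed marker order is an integer vector of +/- marker ids describing
# one linear chromosome left-telomere-first. Marker m has extremities
# tail = 2m-1 and head = 2m; a gene +m is traversed tail->head. The
# adjacency set is represented as a partner vector over the 2n
# extremities (partner 0 = telomere).

order_to_partner <- function(ord) {
  n <- length(ord)
  partner <- integer(2L * n)
  entry <- function(g) if (g > 0) 2L * g - 1L else -2L * g
  exit <- function(g) if (g > 0) 2L * g else -2L * g - 1L
  if (n >= 2) {
    for (i in seq_len(n - 1L)) {
      p <- exit(ord[i])
      q <- entry(ord[i + 1L])
      partner[p] <- q
      partner[q] <- p
    }
  }
  partner
}

#' DCJ distance between two signed marker orders
#'
#' Builds the adjacency graph of the two chromosomes over marker
#' extremities and applies the cycle/odd-path formula
#' `d = n - C - I/2`, where `C` is the number of cycles and `I` the
#' number of odd paths. The distance is reversal-invariant: a chromosome
#' read from the other telomere is at distance 0.
#'
#' @param a,b Signed integer vectors over the same marker set (each
#'   marker exactly once, sign = orientation), or a list as returned by
#'   [extract_marker_orders()] (then `b` is omitted).
#' @return One-row tibble of class `dcj_result`: `n_markers`, `n_cycles`,
#'   `n_odd_paths`, `distance`, `normalized`.
#' @export
dcj_distance <- function(a, b = NULL) {
  if (is.list(a) && is.null(b)) {
    b <- a$b
    a <- a$a
  }
  if (!setequal(abs(a), abs(b)) || length(a) != length(b)) {
    stop("marker sets differ between the two orders")
  }
  relabel <- stats::setNames(seq_along(a), abs(a))
  a2 <- sign(a) * relabel[as.character(abs(a))]
  b2 <- sign(b) * relabel[as.character(abs(b))]
  n <- length(a2)
  pa <- order_to_partner(a2)
  pb <- order_to_partner(b2)

  visited <- logical(2L * n)
  cycles <- 0L
  odd_paths <- 0L
  for (e0 in seq_len(2L * n)) {
    if (visited[e0]) next
    # collect the component of e0 under the links pa, pb
    comp <- integer(0)
    stack <- e0
    while (length(stack) > 0) {
      e <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (visited[e]) next
      visited[e] <- TRUE
      comp <- c(comp, e)
      for (nx in c(pa[e], pb[e])) {
        if (nx > 0 && !visited[nx]) stack <- c(stack, nx)
      }
    }
    is_path <- any(pa[comp] == 0L) || any(pb[comp] == 0L)
    if (!is_path) {
      cycles <- cycles + 1L
    } else if (length(comp) %% 2L == 1L) {
      odd_paths <- odd_paths + 1L
    }
  }
  dist <- n - cycles - odd_paths / 2
  structure(
    tibble::tibble(
      n_markers = n, n_cycles = cycles, n_odd_paths = odd_paths,
      distance = dist, normalized = dist / n
    ),
    class = c("dcj_result", class(tibble::tibble()))
  )
}

#' Normalize a DCJ distance by marker count
#'
#' @param result A `dcj_result` from [dcj_distance()].
#' @return `distance / n_markers`.
#' @export
normalized_dcj <- function(result) {
  if (result$n_markers < 1) stop("no markers")
  result$distance / result$n_markers
}

#' Extract signed marker orders for a genome pair
#'
#' Restricts both chromosomes to the mapped genes (optionally a subset of
#' them), relabels the markers 1..n by rank in `a`, and records each
#' marker's orientation from the gene strand with both chromosomes
#' oriented left-telomere-first.
#'
#' @param a,b [linear_chromosome()] objects.
#' @param map An [orthology_map()] (`gene_a` in `a`, `gene_b` in `b`).
#' @param subset Optional character vector of `a` gene ids to keep.
#' @return List with signed integer vectors `a` and `b`.
#' @export
extract_marker_orders <- function(a, b, map, subset = NULL) {
  m <- map
  if (!is.null(subset)) m <- m[m$gene_a %in% subset, , drop = FALSE]
  m <- m[m$gene_a %in% a$gene_id & m$gene_b %in% b$gene_id, , drop = FALSE]
  if (nrow(m) == 0) stop("empty marker set after filtering")
  a_idx <- match(m$gene_a, a$gene_id)
  marker <- stats::setNames(rank(a$rank[a_idx]), m$gene_a)
  sign_of <- function(strand) ifelse(strand == "+", 1L, -1L)

  ord_a <- order(a$rank[a_idx])
  sa <- as.integer(marker[m$gene_a[ord_a]]) *
    sign_of(a$strand[a_idx][ord_a])

  b_idx <- match(m$gene_b, b$gene_id)
  ord_b <- order(b$rank[b_idx])
  sb <- as.integer(marker[m$gene_a[ord_b]]) *
    sign_of(b$strand[b_idx][ord_b])
  list(a = as.integer(sa), b = as.integer(sb))
}

# --- breadth-first-search reference implementation -----------------------

partner_key <- function(partner) intToUtf8(partner + 1L)

dcj_neighbours <- function(partner) {
  n2 <- length(partner)
  edges <- lapply(which(seq_len(n2) < partner), function(p) {
    c(p, partner[p])
  })
  telo <- which(partner == 0L)
  out <- list()
  add <- function(st) out[[length(out) + 1L]] <<- st
  ne <- length(edges)
  # rejoin two adjacencies (two ways)
  if (ne >= 2) {
    for (i in seq_len(ne - 1L)) {
      for (j in seq.int(i + 1L, ne)) {
        p <- edges[[i]][1]; q <- edges[[i]][2]
        r <- edges[[j]][1]; s <- edges[[j]][2]
        st <- partner
        st[p] <- r; st[r] <- p; st[q] <- s; st[s] <- q
        add(st)
        st <- partner
        st[p] <- s; st[s] <- p; st[q] <- r; st[r] <- q
        add(st)
      }
    }
  }
  # adjacency + telomere
  for (e in edges) {
    for (t in telo) {
      p <- e[1]; q <- e[2]
      st <- partner
      st[p] <- t; st[t] <- p; st[q] <- 0L
      add(st)
      st <- partner
      st[q] <- t; st[t] <- q; st[p] <- 0L
      add(st)
    }
  }
  # split an adjacency into two telomeres
  for (e in edges) {
    st <- partner
    st[e[1]] <- 0L; st[e[2]] <- 0L
    add(st)
  }
  # join two telomeres
  nt <- length(telo)
  if (nt >= 2) {
    for (i in seq_len(nt - 1L)) {
      for (j in seq.int(i + 1L, nt)) {
        st <- partner
        st[telo[i]] <- telo[j]; st[telo[j]] <- telo[i]
        add(st)
      }
    }
  }
  out
}

#' Exhaustive BFS distances from a signed marker order
#'
#' Breadth-first search over genuine DCJ operations (cutting and
#' rejoining adjacencies and telomeres), enumerating every genome
#' structure reachable from `a` and its minimal operation count. This is
#' a reference implementation, independent of the [dcj_distance()]
#' formula, intended for small marker counts.
#'
#' @param a Signed integer marker order.
#' @return An environment mapping the adjacency-set key of every
#'   reachable genome to its minimal DCJ operation count from `a`.
#'   Look up a target order with [dcj_distance_search()], or directly via
#'   `env[[linsyn:::partner_key(linsyn:::order_to_partner(b))]]`.
#' @export
dcj_bfs_distances <- function(a) {
  start <- order_to_partner(as.integer(a))
  dist <- new.env(parent = emptyenv(), size = 4096L)
  assign(partner_key(start), 0L, envir = dist)
  frontier <- list(start)
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    nxt <- list()
    for (st in frontier) {
      for (nb in dcj_neighbours(st)) {
        k <- partner_key(nb)
        if (is.null(dist[[k]])) {
          dist[[k]] <- d
          nxt[[length(nxt) + 1L]] <- nb
        }
      }
    }
    frontier <- nxt
  }
  dist
}

#' BFS-based DCJ distance (reference oracle)
#'
#' Shortest DCJ operation count from `a` to `b` by breadth-first search,
#' stopping as soon as the target adjacency set is reached. Exponential in
#' marker count; use for small instances only.
#'
#' @param a,b Signed integer vectors over the same marker set.
#' @param precomputed Optionally, the environment from
#'   [dcj_bfs_distances()]`(a)` to answer many queries against one source.
#' @return Integer distance.
#' @export
dcj_distance_search <- function(a, b, precomputed = NULL) {
  if (!setequal(abs(a), abs(b))) stop("marker sets differ")
  relabel <- stats::setNames(seq_along(a), abs(a))
  a2 <- as.integer(sign(a) * relabel[as.character(abs(a))])
  b2 <- as.integer(sign(b) * relabel[as.character(abs(b))])
  target <- partner_key(order_to_partner(b2))
  if (!is.null(precomputed)) {
    d <- precomputed[[target]]
    if (is.null(d)) stop("target not reachable in precomputed table")
    return(as.integer(d))
  }
  start <- order_to_partner(a2)
  if (partner_key(start) == target) return(0L)
  seen <- new.env(parent = emptyenv(), size = 4096L)
  assign(partner_key(start), TRUE, envir = seen)
  frontier <- list(start)
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    nxt <- list()
    for (st in frontier) {
      for (nb in dcj_neighbours(st)) {
        k <- partner_key(nb)
        if (k == target) return(d)
        if (is.null(seen[[k]])) {
          seen[[k]] <- TRUE
          nxt[[length(nxt) + 1L]] <- nb
        }
      }
    }
    frontier <- nxt
  }
  stop("target unreachable")  # cannot happen for equal marker sets
}

#' Category-wise normalized DCJ against a set of genomes
#'
#' Splits the reference's mapped genes into three categories — core
#' genes, non-core orthologues inside the core-region, and orthologues in
#' the chromosomal arms — and computes the normalized DCJ distance of
#' each category against every compared genome, together with the
#' cophenetic distance from the tree.
#'
#' @param ref Reference [linear_chromosome()].
#' @param others Named list of compared chromosomes.
#' @param maps Named list of [orthology_map()]s keyed like `others`.
#' @param is_core Logical vector over `ref` rows (rank order irrelevant;
#'   aligned to `ref$gene_id`).
#' @param region A [core_region()] row for the reference.
#' @param tree Optional [ape::phylo] for cophenetic distances.
#' @return Tibble: `other`, `category`, `n_markers`, `distance`,
#'   `normalized`, `cophenetic_distance` (`NA` rows for empty categories).
#' @export
category_dcj_scan <- function(ref, others, maps, is_core, region,
                              tree = NULL) {
  core_ids <- ref$gene_id[is_core]
  in_region <- ref$rank >= region$start_rank & ref$rank <= region$end_rank
  cats <- list(
    core = core_ids,
    noncore_region = ref$gene_id[!is_core & in_region],
    arms = ref$gene_id[!in_region]
  )
  d <- if (!is.null(tree)) {
    cophenetic_matrix(tree)[chrom_genome_id(ref), ]
  } else NULL
  rows <- list()
  for (id in names(others)) {
    for (cat in names(cats)) {
      sub <- intersect(cats[[cat]], maps[[id]]$gene_a)
      if (length(sub) == 0) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          other = id, category = cat, n_markers = 0L,
          distance = NA_real_, normalized = NA_real_,
          cophenetic_distance = if (is.null(d)) NA_real_ else d[[id]]
        )
        next
      }
      orders <- extract_marker_orders(ref, others[[id]], maps[[id]],
                                      subset = sub)
      res <- dcj_distance(orders)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        other = id, category = cat, n_markers = res$n_markers,
        distance = res$distance, normalized = res$normalized,
        cophenetic_distance = if (is.null(d)) NA_real_ else d[[id]]
      )
    }
  }
  dplyr::bind_rows(rows)
}
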