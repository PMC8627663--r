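# Portion-wise evolutionary-rate analysis: equal-gene chromosome portions,
# per-portion synteny indexes against phylogenetic distance, polynomial
# trend fits and early-divergence slopes.

#' Cophenetic distance matrix of a phylogeny
#'
#' `d(i, j)` is the sum of branch lengths along the tree path between
#' leaves `i` and `j`.
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @return Symmetric numeric matrix with leaf labels as dimnames.
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  m <- ape::cophenetic.phylo(tree)
  m[tree$tip.label, tree$tip.label]
}

#' Split a chromosome into k equal-gene portions
#'
#' Contiguous rank blocks of `floor(n/k)` or `ceiling(n/k)` genes; the
#' `n %% k` remainder genes are distributed one each to the last
#' portions, so sizes differ by at most 1 and the portions partition the
#' ranks.
#'
#' @param chrom A [linear_chromosome()].
#' @param k Portion count (e.g. 6, 10, 25, 100).
#' @return Tibble: `portion` (1..k), `start_rank`, `end_rank`, `n_genes`.
#' @export
split_portions <- function(chrom, k) {
  n <- nrow(chrom)
  k <- as.integer(k)
  if (k > n) stop("more portions than genes")
  base <- n %/% k
  r <- n %% k
  sizes <- rep(base, k)
  if (r > 0) sizes[seq.int(k - r + 1L, k)] <- base + 1L
  ends <- cumsum(sizes)
  tibble::tibble(
    portion = seq_len(k),
    start_rank = as.integer(ends - sizes),  # ranks are 0-based
    end_rank = as.integer(ends - 1L),
    n_genes = as.integer(sizes)
  )
}

#' Per-portion OR/GOC values against a set of genomes
#'
#' Computes the chosen index over each portion treated as a single window
#' (no sliding) for every compared genome. GOC is `NA` for a portion with
#' no mapped gene.
#'
#' @param ref Reference [linear_chromosome()].
#' @param others Named list of compared chromosomes.
#' @param maps Named list of [orthology_map()]s keyed like `others`.
#' @param scheme A [split_portions()] table.
#' @param index_kind `"OR"` or `"GOC"`.
#' @param tree Optional [ape::phylo]; adds a `cophenetic_distance` column.
#' @return Tibble: `portion`, `other`, `value`
#'   (+ `cophenetic_distance` when a tree is given).
#' @export
portion_index_scan <- function(ref, others, maps, scheme,
                               index_kind = c("OR", "GOC"), tree = NULL) {
  index_kind <- match.arg(index_kind)
  d <- if (!is.null(tree)) {
    cophenetic_matrix(tree)[chrom_genome_id(ref), ]
  } else NULL
  rows <- lapply(names(others), function(id) {
    fl <- synteny_flags(ref, others[[id]], maps[[id]])
    vals <- vapply(seq_len(nrow(scheme)), function(p) {
      in_p <- fl$rank >= scheme$start_rank[p] & fl$rank <= scheme$end_rank[p]
      if (index_kind == "OR") {
        mean(fl$mapped[in_p])
      } else {
        den <- sum(fl$mapped[in_p])
        if (den == 0) NA_real_ else sum(fl$mapped[in_p] & fl$in_pair[in_p]) / den
      }
    }, numeric(1))
    out <- tibble::tibble(portion = scheme$portion, other = id, value = vals)
    if (!is.null(d)) out$cophenetic_distance <- d[[id]]
    out
  })
  dplyr::bind_rows(rows)
}

#' Fit a polynomial trend and the early-divergence slope
#'
#' Least-squares polynomial of the given degree for index values against
#' phylogenetic distance, plus the early slope `alpha`: the slope of an
#' ordinary linear fit restricted to points with distance inside
#' `early_range` (0 to 0.1 by default). The early slope quantifies how
#' fast an index declines between closely related genomes.
#'
#' @param points Tibble with columns `distance` and `value`.
#' @param degree Polynomial degree (3 for portion trends, 2 for DCJ
#'   trends).
#' @param early_range Distance range for the early linear slope.
#' @return A list of class `trend_fit`: `model` (the polynomial `lm`),
#'   `degree`, `alpha_early`, `n_points`, `n_early`, `points`.
#' @export
fit_trend <- function(points, degree = 3, early_range = c(0, 0.1)) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("distance", "value") %in% names(points)))
  points <- points[stats::complete.cases(points[, c("distance", "value")]), ]
  if (nrow(points) < degree + 1) {
    stop("need at least ", degree + 1, " points for a degree-", degree,
         " fit")
  }
  model <- stats::lm(value ~ poly(distance, degree, raw = TRUE),
                     data = points)
  early <- points[points$distance >= early_range[1] &
                    points$distance <= early_range[2], ]
  alpha <- if (nrow(early) >= 2 && stats::var(early$distance) > 0) {
    if (stats::var(early$value) == 0) 0 else
      unname(stats::coef(stats::lm(value ~ distance, data = early))[2])
  } else NA_real_
  structure(
    list(model = model, degree = degree, alpha_early = alpha,
         n_points = nrow(points), n_early = nrow(early),
         early_range = early_range, points = points),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "degree-%d trend over %d points; early slope alpha = %.4g (%d points in [%g, %g])\n",
    x$degree, x$n_points, x$alpha_early, x$n_early,
    x$early_range[1], x$early_range[2]))
  invisible(x)
}

#' @rdname fit_trend
#' @param x A `trend_fit` object.
#' @param ... Unused.
#' @export
tidy.trend_fit <- function(x, ...) {
  co <- stats::coef(x$model)
  tibble::tibble(term = c(paste0("beta", seq_along(co) - 1), "alpha_early"),
                 estimate = c(unname(co), x$alpha_early))
}

#' @rdname fit_trend
#' @export
glance.trend_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(degree = x$degree, alpha_early = x$alpha_early,
                 r.squared = s$r.squared, n_points = x$n_points,
                 n_early = x$n_early)
}

#' Per-portion trend fits
#'
#' Convenience wrapper: runs [fit_trend()] on each portion of a
#' [portion_index_scan()] table (which must carry `cophenetic_distance`).
#'
#' @param scan Output of [portion_index_scan()] with distances.
#' @param degree,early_range Passed to [fit_trend()].
#' @return Tibble with one row per portion: `portion`, `alpha_early`,
#'   `n_points`, plus a list-column `fit` of `trend_fit` objects.
#' @export
portion_trends <- function(scan, degree = 3, early_range = c(0, 0.1)) {
  stopifnot("cophenetic_distance" %in% names(scan))
  scan |>
    dplyr::group_by(.data$portion) |>
    dplyr::group_modify(function(df, key) {
      fit <- fit_trend(
        tibble::tibble(distance = df$cophenetic_distance, value = df$value),
        degree = degree, early_range = early_range)
      tibble::tibble(alpha_early = fit$alpha_early,
                     n_points = fit$n_points, fit = list(fit))
    }) |>
    dplyr::ungroup()
}
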