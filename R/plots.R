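# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a sliding-window synteny profile
#'
#' OR/GOC profiles are drawn against the chromosomal position of the
#' window's central gene; NOC profiles against the ordinal window number
#' (NOC windows have no fixed physical extent).
#'
#' @param object A `window_profile` from [or_profile()], [goc_profile()]
#'   or [noc_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.window_profile <- function(object, ...) {
  kind <- attr(object, "index_kind")
  df <- tibble::as_tibble(object)
  if ("anchor_bp" %in% names(df)) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$anchor_bp / 1e6,
                                          y = .data$value)) +
      ggplot2::labs(x = "Position of central gene (Mb)")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$window,
                                          y = .data$value)) +
      ggplot2::labs(x = "Window (ordinal)")
  }
  p +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      y = kind,
      title = sprintf("%s: %s vs %s", kind, attr(object, "ref"),
                      attr(object, "other")),
      subtitle = paste("window:", attr(object, "window_spec"))
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of percentile-binned profiles across genomes
#'
#' @param tbl Output of [profile_heatmap_table()].
#' @param index_kind Label for the fill legend.
#' @return A ggplot; rows (compared genomes) are ordered from the
#'   phylogenetically closest to the farthest, missing values are drawn
#'   grey.
#' @export
plot_profile_heatmap <- function(tbl, index_kind = "GOC") {
  lv <- unique(tbl$other[order(tbl$cophenetic_distance)])
  tbl$other <- factor(tbl$other, levels = rev(lv))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$bin, y = .data$other,
                                    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "red", high = "blue",
                                 limits = c(0, 1), na.value = "grey80",
                                 name = index_kind) +
    ggplot2::labs(x = "Percent of reference chromosome",
                  y = "Compared genome (closest at top)") +
    ggplot2::theme_minimal()
}

#' Box-and-whisker rarefaction plot of pan- and core-genome sizes
#'
#' @param records A [rarefaction()] table.
#' @return A ggplot with one box per genome-subset size for each of the
#'   pan- and core-genome.
#' @export
plot_rarefaction <- function(records) {
  long <- records |>
    tidyr::pivot_longer(c("core_size", "pan_size"), names_to = "set",
                        values_to = "size") |>
    dplyr::mutate(set = ifelse(.data$set == "core_size", "core-genome",
                               "pan-genome"))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$n), y = .data$size,
                                     fill = .data$set)) +
    ggplot2::geom_boxplot(outlier.size = 0.3, linewidth = 0.2) +
    ggplot2::labs(x = "Genomes sampled", y = "Gene families",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a polynomial trend fit with its early-slope segment
#'
#' @param object A `trend_fit` from [fit_trend()].
#' @param ... Unused.
#' @return A ggplot: points, the fitted polynomial with its 95 %
#'   confidence band, and the early-range linear slope.
#' @export
autoplot.trend_fit <- function(object, ...) {
  pts <- object$points
  grid <- tibble::tibble(
    distance = seq(min(pts$distance), max(pts$distance), length.out = 200))
  pred <- stats::predict(object$model, newdata = grid,
                         interval = "confidence", level = 0.95)
  grid$fit <- pred[, "fit"]
  grid$lwr <- pred[, "lwr"]
  grid$upr <- pred[, "upr"]
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$distance,
                                         y = .data$value)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_ribbon(
      data = grid,
      ggplot2::aes(x = .data$distance, ymin = .data$lwr, ymax = .data$upr),
      inherit.aes = FALSE, fill = "grey70", alpha = 0.5) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$distance, y = .data$fit),
                       inherit.aes = FALSE, colour = "steelblue")
  if (is.finite(object$alpha_early)) {
    early <- pts[pts$distance >= object$early_range[1] &
                   pts$distance <= object$early_range[2], ]
    if (nrow(early) >= 2) {
      lf <- stats::lm(value ~ distance, data = early)
      seg <- tibble::tibble(
        distance = range(early$distance),
        value = stats::predict(lf, tibble::tibble(
          distance = range(early$distance))))
      p <- p + ggplot2::geom_line(
        data = seg, ggplot2::aes(x = .data$distance, y = .data$value),
        inherit.aes = FALSE, colour = "firebrick", linetype = 2)
    }
  }
  p +
    ggplot2::labs(
      x = "Cophenetic distance", y = "Index value",
      subtitle = sprintf("degree %d; early slope alpha = %.3g",
                         object$degree, object$alpha_early)) +
    ggplot2::theme_minimal()
}

#' Plot category-wise normalized DCJ against phylogenetic distance
#'
#' @param scan Output of [category_dcj_scan()].
#' @return A ggplot with one colour per gene category and a degree-2
#'   trend per category.
#' @export
plot_category_dcj <- function(scan) {
  df <- scan[stats::complete.cases(scan[, c("normalized",
                                            "cophenetic_distance")]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cophenetic_distance,
                                   y = .data$normalized,
                                   colour = .data$category,
                                   shape = .data$category)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm",
                         formula = y ~ poly(x, 2, raw = TRUE),
                         se = TRUE, level = 0.95, linewidth = 0.6) +
    ggplot2::labs(x = "Cophenetic distance", y = "Normalized DCJ distance",
                  colour = "Gene category", shape = "Gene category") +
    ggplot2::theme_minimal()
}
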