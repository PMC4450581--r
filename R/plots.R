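#' @importFrom ggplot2 ggplot aes geom_raster geom_point geom_line geom_ribbon
#'   facet_wrap labs scale_fill_manual theme_minimal scale_x_log10 scale_y_log10
NULL

#' Matrix portrait of a bipartite graph
#'
#' Filled cells are links; with `ranked = TRUE` rows and columns are first
#' reordered by decreasing fitness / increasing complexity, which renders a
#' nested matrix as a triangle.
#'
#' @param object a [bipartite_graph()].
#' @param ranked reorder by fitness-complexity before drawing.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bipartite_graph <- function(object, ranked = FALSE, ...) {
  g <- if (ranked) rank_by_fitness(object) else object
  m <- biadjacency(g)
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$link <- factor(m[cbind(df$row, df$col)])
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$link)) +
    geom_raster() +
    scale_fill_manual(values = c(`0` = "white", `1` = "#2166ac"), guide = "none") +
    ggplot2::scale_y_reverse() +
    labs(x = "column nodes", y = "row nodes") +
    theme_minimal()
}

#' Assortativity scatter: nearest-neighbour degree versus degree
#'
#' @param object an [assortativity_profile()].
#' @param ... unused.
#' @return a ggplot faceted by layer (ANPU vs diversification, ANCD vs
#'   ubiquity); a decreasing trend signals disassortative mixing.
#' @export
autoplot.assortativity_profile <- function(object, ...) {
  df <- dplyr::filter(object$nodes, !is.na(.data$value))
  ggplot(df, aes(x = .data$degree, y = .data$value)) +
    geom_point(alpha = 0.6, colour = "#2166ac") +
    facet_wrap(~measure, scales = "free") +
    labs(x = "degree", y = "average nearest-neighbour degree") +
    theme_minimal()
}

#' Observed versus expected per-node values with ensemble bands
#'
#' Per-node ANPU/ANCD against degree, with the ensemble mean and shaded 1 and
#' 2 standard-deviation bands; points falling outside the 2-sd band are not
#' explained by the null model.
#'
#' @param object an [observable_report()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.observable_report <- function(object, ...) {
  df <- dplyr::filter(object$nodes, !is.na(.data$value))
  ggplot(df, aes(x = .data$degree)) +
    geom_ribbon(
      aes(
        ymin = .data$expected - 2 * .data$sd,
        ymax = .data$expected + 2 * .data$sd
      ),
      fill = "grey80"
    ) +
    geom_ribbon(
      aes(
        ymin = .data$expected - .data$sd,
        ymax = .data$expected + .data$sd
      ),
      fill = "grey60"
    ) +
    geom_point(aes(y = .data$value), colour = "#2166ac", alpha = 0.6) +
    geom_line(aes(y = .data$expected), colour = "black") +
    facet_wrap(~measure, scales = "free") +
    labs(x = "degree", y = "observed (points) vs expected (line, bands)") +
    theme_minimal()
}

#' Fitness-complexity rank curves, observed versus ensemble
#'
#' @param object an [observable_report()] computed with
#'   `include_fitness = TRUE`.
#' @param ... unused.
#' @return a ggplot of rank-averaged fitness and complexity with 2-sd bands.
#' @export
plot_rank_curves <- function(object, ...) {
  stopifnot(inherits(object, "observable_report"))
  if (is.null(object$ranks)) {
    abort("report has no rank curves: rerun observable_report(include_fitness = TRUE)")
  }
  df <- dplyr::filter(object$ranks, !is.na(.data$observed))
  ggplot(df, aes(x = .data$rank)) +
    geom_ribbon(
      aes(
        ymin = pmax(.data$expected - 2 * .data$sd, 1e-12),
        ymax = .data$expected + 2 * .data$sd
      ),
      fill = "grey80"
    ) +
    geom_line(aes(y = .data$expected), colour = "black") +
    geom_point(aes(y = .data$observed), colour = "#2166ac", size = 0.8) +
    facet_wrap(~layer, scales = "free") +
    scale_y_log10() +
    labs(x = "rank", y = "score (log scale)") +
    theme_minimal()
}
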