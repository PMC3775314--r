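#' Forest plot of a pooled random-effects meta-analysis
#'
#' Per-study Hedges' g with 95% confidence intervals and the pooled
#' estimate as the bottom row, with point size proportional to
#' random-effects weight.
#'
#' @param object a `pooled_effect`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pooled_effect <- function(object, ...) {
  dat <- forest_data(object)
  dat$study <- factor(dat$study, levels = rev(dat$study))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$g, y = .data$study)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight,
                                     shape = .data$pooled)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18),
                                guide = "none") +
    ggplot2::scale_size_continuous(range = c(2, 5), guide = "none") +
    ggplot2::labs(x = "Hedges' g (MDD - control)", y = NULL,
                  title = "Random-effects meta-analysis") +
    ggplot2::theme_minimal()
}

#' Plot a thresholded co-expression network
#'
#' Fruchterman-Reingold layout with edge transparency proportional to
#' correlation strength, so tightly co-expressed modules cluster visually.
#'
#' @param object a `gene_network`.
#' @param highlight optional genes to highlight (e.g. the core module).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gene_network <- function(object, highlight = NULL, ...) {
  g <- as_igraph(object)
  set.seed(1)  # layout only; analysis results never depend on this
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(
    gene = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
    highlighted = igraph::V(g)$name %in% (highlight %||% character(0))
  )
  edges <- object$edges
  edges$x <- nodes$x[match(edges$from, nodes$gene)]
  edges$y <- nodes$y[match(edges$from, nodes$gene)]
  edges$xend <- nodes$x[match(edges$to, nodes$gene)]
  edges$yend <- nodes$y[match(edges$to, nodes$gene)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, alpha = .data$weight),
      color = "steelblue") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$highlighted),
      size = 3) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$gene),
      vjust = -1, size = 3) +
    ggplot2::scale_color_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
      guide = "none") +
    ggplot2::scale_alpha_continuous(range = c(0.2, 0.9), guide = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste0("Co-expression network (r > ",
                                 object$threshold, ")"))
}

#' Cell-mean plot for one FCG endpoint
#'
#' Mean +/- SEM per genotype-by-treatment cell, faceted by gonadal sex.
#'
#' @param object an `fcg_anova`.
#' @param endpoints the endpoint table the model was fitted on.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fcg_anova <- function(object, endpoints, ...) {
  dat <- endpoints[!is.na(endpoints[[object$endpoint]]), ]
  dat$.y <- dat[[object$endpoint]]
  cells <- dplyr::summarise(
    dplyr::group_by(dat, .data$genetic_sex, .data$gonadal_sex,
                    .data$treatment),
    mean = mean(.data$.y), sem = stats::sd(.data$.y) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$genetic_sex,
                                      y = .data$mean,
                                      fill = .data$treatment)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(0.9), width = 0.25) +
    ggplot2::facet_wrap(~gonadal_sex, labeller = ggplot2::label_both) +
    ggplot2::labs(y = object$endpoint, x = "genetic sex",
                  title = paste("FCG cell means:", object$endpoint)) +
    ggplot2::theme_minimal()
}
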