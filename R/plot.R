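#' Plot a bipartite metabolic graph
#'
#' Reactions render as squares, metabolites as circles (the conventional
#' bipartite rendering); an optional pathway is highlighted.
#'
#' @param object a `bipartite_graph`.
#' @param highlight optional character vector of reaction ids to emphasise.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bipartite_graph <- function(object, highlight = NULL, ...) {
  ig <- as_igraph(object)
  set.seed(1L)  # layout only; the graph itself is deterministic
  xy <- igraph::layout_with_fr(ig)
  nodes <- tibble(
    name = igraph::V(ig)$name,
    type = igraph::V(ig)$bipartite,
    x = xy[, 1], y = xy[, 2]
  )
  nodes$highlight <- nodes$name %in% (highlight %||% character(0))
  ed <- graph_edges(object)
  ed <- dplyr::left_join(ed, nodes[, c("name", "x", "y")],
                         by = c(from = "name"))
  ed <- dplyr::left_join(ed, nodes[, c("name", "x", "y")],
                         by = c(to = "name"), suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x_to, yend = .data$y_to),
      colour = "grey70",
      arrow = ggplot2::arrow(length = ggplot2::unit(1.6, "mm"))) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$type,
                   colour = .data$highlight), size = 3) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      vjust = -1, size = 2.8) +
    ggplot2::scale_shape_manual(values = c(metabolite = 16, reaction = 15)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(shape = NULL)
}

#' @describeIn enumerate_pathways bar chart of pathway counts per size over
#'   all scoped metabolites (columns up to `beta`).
#' @param object a `pathway_table`.
#' @export
autoplot.pathway_table <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$size >= 1, ]
  agg <- td |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(n_pathways = sum(.data$n_pathways), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$size, y = .data$n_pathways)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "pathway size (reactions)", y = "pathways stored",
                  title = paste0("Pathway inventory up to beta = ",
                                 object$beta)) +
    ggplot2::theme_minimal()
}
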