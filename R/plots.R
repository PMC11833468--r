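#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an evaluation report
#'
#' Bar chart of the metric battery per 4M class, with the kappa performance
#' gate marked on the kappa panels.
#'
#' @param object A `fourms_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fourms_eval <- function(object, ...) {
  d <- tidy(object)
  gate_d <- tibble::tibble(
    metric = c("kappa", "kappa_binned"), yintercept = object$gate
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$m_class, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(
      data = gate_d, ggplot2::aes(yintercept = .data$yintercept),
      linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Extraction agreement by class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot taxonomy cluster sizes
#'
#' Horizontal bars of expression counts per level-1 cluster, faceted by
#' class — the shape of the taxonomy's first level.
#'
#' @param object A `fourms_taxonomy`.
#' @param level Hierarchy level to display (default 1).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fourms_taxonomy <- function(object, level = 1, ...) {
  d <- tidy(object)
  d <- d[d$level == level, ]
  d$label <- ifelse(is.na(d$label), d$node_id, d$label)
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = .data$n_members, y = stats::reorder(.data$label, .data$n_members)
    )
  ) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::facet_wrap(~m_class, scales = "free_y") +
    ggplot2::labs(
      x = "expressions", y = NULL,
      title = paste0("Level-", level, " clusters")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a concept graph
#'
#' Static network rendering of a [query_concept()] result with a fixed
#' layout seed, class roots emphasised.
#'
#' @param object A `fourms_graph`.
#' @param layout_seed Seed for the force-directed layout.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fourms_graph <- function(object, layout_seed = 42, ...) {
  if (nrow(object$nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void())
  }
  vert <- as.data.frame(object$nodes)
  names(vert)[1] <- "name"
  g <- igraph::graph_from_data_frame(
    as.data.frame(object$edges), directed = TRUE, vertices = vert
  )
  xy <- withr::with_seed(layout_seed, igraph::layout_with_fr(g))
  d <- tibble::tibble(
    x = xy[, 1], y = xy[, 2],
    kind = igraph::V(g)$kind, label = igraph::V(g)$label,
    m_class = igraph::V(g)$m_class, name = igraph::V(g)$name
  )
  ed <- tibble::as_tibble(igraph::as_data_frame(g, what = "edges"))
  ed$x <- d$x[match(ed$from, d$name)]
  ed$y <- d$y[match(ed$from, d$name)]
  ed$xend <- d$x[match(ed$to, d$name)]
  ed$yend <- d$y[match(ed$to, d$name)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend
      ),
      colour = "grey70"
    ) +
    ggplot2::geom_point(
      data = d,
      ggplot2::aes(
        x = .data$x, y = .data$y, colour = .data$m_class,
        size = .data$kind == "class_root"
      )
    ) +
    ggplot2::geom_text(
      data = d[d$kind != "expression", ],
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      size = 3, vjust = -1
    ) +
    ggplot2::scale_size_manual(values = c(2, 5), guide = "none") +
    ggplot2::labs(
      title = paste0("Concept network: '", object$query_term, "'"),
      colour = "class"
    ) +
    ggplot2::theme_void()
}

#' Plot a linkage dendrogram
#'
#' @param x A `fourms_linkage`.
#' @param ... Passed to [stats::plot.hclust] via the base plot method.
#' @importFrom graphics plot plot.new title
#' @export
plot.fourms_linkage <- function(x, ...) {
  if (x$n_leaves < 2) {
    graphics::plot.new()
    graphics::title("single leaf")
    return(invisible(x))
  }
  plot(stats::as.hclust(x), ...)
  invisible(x)
}
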