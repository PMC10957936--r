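# ggplot2 displays: tier-layered graph drawing and edge-stability plots.

tier_layout <- function(g) {
  tiers <- g$tiers %||% setNames(rep(0L, length(g$nodes)), g$nodes)
  tibble(node = g$nodes, tier = unname(tiers[g$nodes])) |>
    dplyr::group_by(.data$tier) |>
    dplyr::arrange(.data$node, .by_group = TRUE) |>
    dplyr::mutate(y = seq_along(.data$node) - (dplyr::n() + 1) / 2) |>
    dplyr::ungroup()
}

#' Plot an mpdag in tier-layered layout
#'
#' Nodes are placed column-wise by tier; directed edges carry arrowheads,
#' undirected edges none.
#'
#' @param object An [mpdag()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mpdag <- function(object, ...) {
  lay <- tier_layout(object)
  e <- mpdag_edges(object)
  seg <- dplyr::left_join(e, lay, by = c("from" = "node")) |>
    dplyr::rename(x = "tier", y0 = "y") |>
    dplyr::left_join(lay, by = c("to" = "node")) |>
    dplyr::rename(xend = "tier", yend = "y")
  p <- ggplot2::ggplot()
  if (nrow(seg)) {
    dirseg <- seg[seg$mark == "directed", ]
    undseg <- seg[seg$mark == "undirected", ]
    if (nrow(undseg)) {
      p <- p + ggplot2::geom_segment(
        data = undseg,
        ggplot2::aes(x = .data$x, y = .data$y0, xend = .data$xend, yend = .data$yend),
        colour = "grey55", linewidth = 0.4)
    }
    if (nrow(dirseg)) {
      p <- p + ggplot2::geom_segment(
        data = dirseg,
        ggplot2::aes(x = .data$x, y = .data$y0, xend = .data$xend, yend = .data$yend),
        colour = "grey25", linewidth = 0.4,
        arrow = ggplot2::arrow(length = ggplot2::unit(5, "pt"), type = "closed"))
    }
  }
  p +
    ggplot2::geom_label(data = lay,
                        ggplot2::aes(x = .data$tier, y = .data$y, label = .data$node),
                        size = 2.8) +
    ggplot2::scale_x_continuous(breaks = unique(lay$tier)) +
    ggplot2::labs(x = "tier", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
}

#' Plot edge stability frequencies of a bootstrap ensemble
#'
#' Shows, for the most stable node pairs, the fraction of bootstrap graphs
#' containing the edge, split by mark.
#'
#' @param object A `graph_ensemble`.
#' @param top Number of pairs displayed (by skeleton frequency).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.graph_ensemble <- function(object, top = 30, ...) {
  freq <- edge_frequencies(object) |>
    dplyr::filter(.data$freq > 0) |>
    dplyr::arrange(dplyr::desc(.data$freq)) |>
    head(top) |>
    dplyr::mutate(pair = paste(.data$from, "-", .data$to)) |>
    tidyr::pivot_longer(dplyr::all_of(c("freq_forward", "freq_backward",
                                        "freq_undirected")),
                        names_to = "mark", values_to = "fraction")
  ggplot2::ggplot(freq, ggplot2::aes(x = stats::reorder(.data$pair, .data$fraction,
                                                        FUN = sum),
                                     y = .data$fraction, fill = .data$mark)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of bootstrap graphs",
                  fill = "orientation") +
    ggplot2::theme_minimal()
}
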