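# Graph comparison and description: Hamming distances, summaries,
# ensemble edge frequencies and consensus graphs.

check_same_nodes <- function(g1, g2) {
  if (!setequal(g1$nodes, g2$nodes)) abort("graphs must share the same node set")
}

# per-pair edge status code on a common sorted node order:
# 0 absent, 1 a->b, 2 b->a, 3 a--b (a < b lexicographically)
pair_status <- function(g, nodes) {
  a <- g$amat[nodes, nodes]
  ut <- upper.tri(a)
  fw <- a[ut]; bw <- t(a)[ut]
  fw + 2L * bw  # 0 none, 1 a->b, 2 b->a, 3 undirected
}

#' Hamming distance between two graphs
#'
#' The number of node pairs adjacent in exactly one of the two graphs;
#' orientation is ignored.
#'
#' @param g1,g2 [mpdag()]s on the same node set.
#' @return Integer count.
#' @export
hamming <- function(g1, g2) {
  check_same_nodes(g1, g2)
  nodes <- sort(g1$nodes)
  sum((pair_status(g1, nodes) > 0) != (pair_status(g2, nodes) > 0))
}

#' Structural Hamming distance between two graphs
#'
#' The number of node pairs whose edge status differs when orientation
#' marks are distinguished: absent, `a -> b`, `b -> a` and `a -- b` are
#' four distinct states, each difference costing 1. Always at least the
#' Hamming distance.
#'
#' @param g1,g2 [mpdag()]s on the same node set.
#' @return Integer count.
#' @export
shd <- function(g1, g2) {
  check_same_nodes(g1, g2)
  nodes <- sort(g1$nodes)
  sum(pair_status(g1, nodes) != pair_status(g2, nodes))
}

#' Descriptive characteristics of a graph
#'
#' Edge and undirected-edge counts, degree statistics after dropping
#' isolated nodes, and shortest-path statistics on the skeleton (marks
#' ignored) averaged over connected ordered pairs only -- disconnected
#' pairs are excluded, not counted as infinite.
#'
#' @param g An [mpdag()].
#' @return One-row tibble with `n_edges`, `n_undirected`, `avg_degree`,
#'   `max_degree`, `avg_shortest_path`, `longest_shortest_path`,
#'   `n_singletons`.
#' @export
graph_summary <- function(g) {
  e <- mpdag_edges(g)
  sk <- skeleton_amat(g)
  deg <- rowSums(sk)
  singletons <- sum(deg == 0)
  active <- deg[deg > 0]
  if (nrow(e) == 0) {
    return(tibble(n_edges = 0L, n_undirected = 0L, avg_degree = 0,
                  max_degree = 0, avg_shortest_path = 0,
                  longest_shortest_path = 0, n_singletons = singletons))
  }
  ig <- as_igraph_skeleton(g)
  D <- igraph::distances(ig)
  finite <- is.finite(D) & D > 0
  tibble(
    n_edges = nrow(e),
    n_undirected = sum(e$mark == "undirected"),
    avg_degree = mean(active),
    max_degree = max(active),
    avg_shortest_path = mean(D[finite]),
    longest_shortest_path = max(D[finite]),
    n_singletons = singletons
  )
}

#' Edge frequencies across a graph ensemble
#'
#' For every node pair, the fraction of member graphs in which the pair is
#' adjacent (skeleton frequency) and the fraction carrying each mark; the
#' mark fractions sum to the skeleton frequency.
#'
#' @param ens A `graph_ensemble` (see [run_bootstrap()]) or plain list of
#'   [mpdag()]s on a shared node set.
#' @return Tibble with columns `from`, `to` (`from < to`), `freq`,
#'   `freq_forward` (`from -> to`), `freq_backward`, `freq_undirected`.
#' @export
edge_frequencies <- function(ens) {
  graphs <- ensemble_graphs(ens)
  if (!length(graphs)) abort("ensemble is empty")
  nodes <- sort(graphs[[1]]$nodes)
  for (g in graphs) {
    if (!setequal(g$nodes, nodes)) abort("ensemble members must share a node set")
  }
  B <- length(graphs)
  stat <- vapply(graphs, pair_status, numeric(length(nodes) * (length(nodes) - 1) / 2),
                 nodes = nodes)
  if (is.null(dim(stat))) stat <- matrix(stat, ncol = B)
  idx <- which(upper.tri(diag(length(nodes))), arr.ind = TRUE)
  tibble(
    from = nodes[idx[, 1]], to = nodes[idx[, 2]],
    freq = rowMeans(stat > 0),
    freq_forward = rowMeans(stat == 1),
    freq_backward = rowMeans(stat == 2),
    freq_undirected = rowMeans(stat == 3)
  ) |> dplyr::arrange(.data$from, .data$to)
}

ensemble_graphs <- function(ens) {
  if (inherits(ens, "graph_ensemble")) ens$graphs else ens
}

#' Mean edge uncertainty of a consensus graph
#'
#' This package's summary of how unstable the edges surviving a consensus
#' threshold still are: `100 * mean(1 - freq)` over the node pairs whose
#' skeleton frequency exceeds `threshold` (0 when every surviving edge is
#' unanimous). This is a descriptive statistic defined by this package;
#' treat it as such when comparing with other software.
#'
#' @inheritParams consensus_graph
#' @return A percentage in `[0, 100]` (`NA` if no edge survives).
#' @export
mean_edge_uncertainty <- function(ens, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  freq <- edge_frequencies(ens)
  keep <- freq$freq[freq$freq > threshold]
  if (!length(keep)) return(NA_real_)
  100 * mean(1 - keep)
}

#' Consensus graph of an ensemble
#'
#' Includes every node pair whose skeleton frequency strictly exceeds
#' `threshold`; the edge receives the plurality mark among the member
#' graphs containing it (ties become undirected). The result is validated:
#' a directed cycle or backwards-in-time orientation introduced by
#' plurality voting is downgraded to undirected and logged.
#'
#' @param ens A `graph_ensemble` or list of [mpdag()]s.
#' @param threshold Skeleton-frequency threshold in `(0, 1]`.
#' @return An [mpdag()].
#' @export
consensus_graph <- function(ens, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  graphs <- ensemble_graphs(ens)
  freq <- edge_frequencies(ens)
  tiers <- graphs[[1]]$tiers
  keep <- freq[freq$freq > threshold, ]
  log <- character()
  edges <- purrr::pmap_dfr(keep, function(from, to, freq, freq_forward,
                                          freq_backward, freq_undirected) {
    marks <- c(forward = freq_forward, backward = freq_backward,
               undirected = freq_undirected)
    best <- names(marks)[marks == max(marks)]
    mk <- if (length(best) > 1) "undirected" else best
    a <- from; b <- to
    switch(mk,
      forward = tibble(from = a, to = b, mark = "directed"),
      backward = tibble(from = b, to = a, mark = "directed"),
      undirected = tibble(from = a, to = b, mark = "undirected")
    )
  })
  g <- mpdag(sort(graphs[[1]]$nodes), edges, tiers = tiers)
  # validate: downgrade violations to undirected
  if (!is.null(tiers)) {
    e <- mpdag_edges(g)
    for (k in seq_len(nrow(e))) {
      if (e$mark[k] == "directed" && tiers[[e$from[k]]] > tiers[[e$to[k]]]) {
        g$amat[e$to[k], e$from[k]] <- 1L
        log <- c(log, sprintf("consensus edge %s -> %s pointed back in time; undirected",
                              e$from[k], e$to[k]))
      }
    }
  }
  while (has_directed_cycle(directed_amat(g))) {
    e <- mpdag_edges(g)
    dir_e <- e[e$mark == "directed", ]
    k <- nrow(dir_e)  # break the lexicographically last directed edge
    g$amat[dir_e$to[k], dir_e$from[k]] <- 1L
    log <- c(log, sprintf("consensus cycle: %s -> %s downgraded to undirected",
                          dir_e$from[k], dir_e$to[k]))
  }
  g$log <- log
  g
}
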