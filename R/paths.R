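# MPDAG path queries: possible ancestors, path enumeration, summaries.

#' Possible ancestors (possible causes) of a node
#'
#' A node `x` is a possible ancestor of `y` when the MPDAG contains at
#' least one partially directed path from `x` to `y`: a path on which every
#' edge is either undirected or directed toward `y` (no edge points back
#' toward `x`). Computed by reverse reachability -- repeatedly adding any
#' node with an undirected edge to, or a directed edge into, the current
#' frontier -- so no path enumeration is needed. A node is not its own
#' possible ancestor.
#'
#' @param g An [mpdag()].
#' @param y Target node name.
#' @return Character vector of possible ancestors (sorted).
#' @export
possible_ancestors <- function(g, y) {
  if (!y %in% g$nodes) abort(sprintf("unknown node '%s'", y))
  a <- g$amat
  # step allowed x -> f along directed x->f or undirected x--f: amat[x, f] == 1
  reach <- setNames(rep(FALSE, length(g$nodes)), g$nodes)
  reach[y] <- TRUE
  repeat {
    new <- g$nodes[rowSums(a[, reach, drop = FALSE] == 1L) > 0 & !reach]
    if (!length(new)) break
    reach[new] <- TRUE
  }
  sort(setdiff(g$nodes[reach], y))
}

#' Enumerate simple directed or partially directed paths
#'
#' Depth-first enumeration, visiting neighbours in lexicographic order, of
#' all simple paths from `x` to `y` whose every step is a directed edge
#' toward `y` (`mode = "directed"`) or a directed-toward-`y` or undirected
#' edge (`mode = "partially_directed"`). Enumeration stops silently at
#' `max_len` edges per path and `max_paths` paths; the result's
#' `truncated` flag reports whether any limit was hit.
#'
#' @param g An [mpdag()].
#' @param x,y Source and target node names.
#' @param mode `"partially_directed"` (default) or `"directed"`.
#' @param max_len Maximum path length in edges (default: number of nodes).
#' @param max_paths Maximum number of paths collected (default `1e6`).
#' @return A `path_set`: list with `source`, `target`, `mode`, `paths`
#'   (list of node-name vectors), `truncated`.
#' @export
enumerate_paths <- function(g, x, y, mode = c("partially_directed", "directed"),
                            max_len = NULL, max_paths = 1e6) {
  mode <- match.arg(mode)
  if (!all(c(x, y) %in% g$nodes)) abort("unknown node name(s)")
  if (x == y) abort("`x` and `y` must differ")
  max_len <- max_len %||% length(g$nodes)
  a <- g$amat
  step_ok <- if (mode == "directed") {
    function(u, v) a[u, v] == 1L && a[v, u] == 0L
  } else {
    function(u, v) a[u, v] == 1L
  }
  paths <- list()
  truncated <- FALSE
  on_path <- setNames(rep(FALSE, length(g$nodes)), g$nodes)
  dfs <- function(u, trail) {
    if (length(paths) >= max_paths) { truncated <<- TRUE; return() }
    nbrs <- sort(g$nodes[a[u, ] == 1L & !on_path])
    for (v in nbrs) {
      if (!step_ok(u, v)) next
      if (v == y) {
        if (length(paths) < max_paths) paths[[length(paths) + 1L]] <<- c(trail, v)
        else truncated <<- TRUE
        next
      }
      if (length(trail) >= max_len) { truncated <<- TRUE; next }
      on_path[v] <<- TRUE
      dfs(v, c(trail, v))
      on_path[v] <<- FALSE
    }
  }
  on_path[x] <- TRUE
  dfs(x, x)
  structure(list(source = x, target = y, mode = mode, paths = paths,
                 truncated = truncated), class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf("<path_set> %d %s path(s) %s ~> %s%s\n", length(x$paths),
              x$mode, x$source, x$target,
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' Summarise a set of paths
#'
#' Reports the number of paths, the shortest path, and for every
#' non-endpoint node the fraction of paths visiting it, sorted by
#' decreasing frequency with lexicographic tie-break.
#'
#' @param ps A `path_set` from [enumerate_paths()].
#' @return List with `n_paths`, `shortest_path` (node vector or `NULL`),
#'   `shortest_length` (edges), and `node_frequencies` (tibble `node`,
#'   `fraction`).
#' @export
summarize_paths <- function(ps) {
  n <- length(ps$paths)
  if (n == 0) {
    return(list(n_paths = 0L, shortest_path = NULL, shortest_length = NA_integer_,
                node_frequencies = tibble(node = character(), fraction = numeric())))
  }
  lens <- lengths(ps$paths) - 1L
  shortest <- ps$paths[[which.min(lens)]]
  mids <- unlist(lapply(ps$paths, function(pp) pp[-c(1, length(pp))]))
  freq <- if (length(mids)) {
    counts <- table(mids)
    tibble(node = names(counts), fraction = as.numeric(counts) / n) |>
      dplyr::arrange(dplyr::desc(.data$fraction), .data$node)
  } else {
    tibble(node = character(), fraction = numeric())
  }
  list(n_paths = n, shortest_path = shortest, shortest_length = min(lens),
       node_frequencies = freq)
}
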